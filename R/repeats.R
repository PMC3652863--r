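#' Scan a sequence for exact maximal repeats
#'
#' Finds all maximal exact repeats of length >= \code{minLen}:
#' \itemize{
#'   \item \code{direct}: the same word occurs at two positions
#'     (\code{pos1 < pos2}; occurrences may overlap);
#'   \item \code{inverted}: the reverse complement of the word at \code{pos1}
#'     occurs at \code{pos2} (occurrences must be disjoint, otherwise every
#'     palindromic centre would generate trivial hits);
#'   \item \code{mirror}: the reversed (not complemented) word occurs at
#'     \code{pos2} (occurrences disjoint).
#' }
#' "Maximal" means not extendable on either side; a matched region symmetric
#' about its own centre is trimmed to the longest pair of disjoint
#' occurrences. Matching is exact over A/C/G/T; ambiguity codes never match.
#' The scanner seeds on shared \code{minLen}-mers and extends, so it runs in
#' near-linear time on genome-scale input.
#'
#' @param sequence DNA (character, \link[Biostrings]{DNAString} or
#'   \linkS4class{GenomeRecord}).
#' @param kind \code{"direct"}, \code{"inverted"} or \code{"mirror"}.
#' @param minLen minimum repeat length (>= 2).
#' @return data.frame \code{kind}, \code{pos1}, \code{pos2}, \code{length},
#'   \code{sequence} (the occurrence at \code{pos1}), sorted by length
#'   descending then \code{pos1}.
#' @examples
#' scanRepeats("ACGTACGT", "direct", minLen = 4)
#' scanRepeats("AAAATTTT", "inverted", minLen = 4)
#' @export
scanRepeats <- function(sequence, kind = c("direct", "inverted", "mirror"),
                        minLen = 8L) {
    kind <- match.arg(kind)
    if (is(sequence, "GenomeRecord")) sequence <- genomeSeq(sequence)
    s <- .asDnaChar(sequence)
    minLen <- as.integer(minLen)
    if (minLen < 2L) stop("scanRepeats: minLen must be >= 2")
    hits <- .scan_repeats_cpp(s, kind, minLen)
    if (nrow(hits) == 0L)
        return(data.frame(kind = character(0), pos1 = integer(0),
                          pos2 = integer(0), length = integer(0),
                          sequence = character(0)))
    hits$kind <- rep(kind, nrow(hits))
    hits$sequence <- substring(s, hits$pos1, hits$pos1 + hits$length - 1L)
    hits[, c("kind", "pos1", "pos2", "length", "sequence")]
}

#' Length of the longest exact repeat of a given kind
#'
#' Wrapper over \code{\link{scanRepeats}} with adaptive minimum length:
#' scanning starts at 32 bp and halves until hits are found (0 if no repeat
#' of length >= 2 exists).
#'
#' @inheritParams scanRepeats
#' @return longest repeat length in bp (integer).
#' @export
maxRepeatLength <- function(sequence, kind = c("direct", "inverted",
                                               "mirror")) {
    kind <- match.arg(kind)
    if (is(sequence, "GenomeRecord")) sequence <- genomeSeq(sequence)
    s <- .asDnaChar(sequence)
    m <- min(32L, max(2L, nchar(s) %/% 2L))
    repeat {
        hits <- scanRepeats(s, kind, minLen = m)
        if (nrow(hits) > 0L) return(max(hits$length))
        if (m <= 2L) return(0L)
        m <- max(2L, m %/% 2L)
    }
}
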