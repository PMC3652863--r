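#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet AAString AAStringSet
#'   reverseComplement matchPattern translate readDNAStringSet writeXStringSet
#'   letterFrequency pairwiseAlignment score GENETIC_CODE
#' @importFrom IRanges IRanges reduce width
#' @importFrom S4Vectors isConstant
#' @importFrom stats rbinom rnorm runif setNames
#' @importFrom utils read.delim write.table head tail
#' @useDynLib phageTermini, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.ARCHITECTURES <- c("blunt", "cos_3", "cos_5", "dtr")
.FEATURE_KINDS <- c("CDS", "tRNA", "gene", "other")

.emptyFeatures <- function() {
    data.frame(kind = character(0), start = integer(0), end = integer(0),
               strand = character(0), label = character(0),
               product = character(0), wraps = logical(0),
               stringsAsFactors = FALSE)
}

#' GenomeRecord: a sequence with typed annotation features
#'
#' A genome (or contig) sequence together with its annotation features
#' (CDS, tRNA, gene) in 1-based inclusive coordinates, plus a topology flag.
#' Circular records may carry origin-wrapping features (start > end), flagged
#' in the \code{wraps} column.
#'
#' @slot id accession or identifier string.
#' @slot sequence a \link[Biostrings]{DNAString} (uppercased IUPAC codes).
#' @slot topology \code{"linear"} or \code{"circular"}.
#' @slot features data.frame with columns \code{kind}, \code{start},
#'   \code{end}, \code{strand}, \code{label}, \code{product}, \code{wraps}.
#' @exportClass GenomeRecord
setClass("GenomeRecord",
    representation(id = "character", sequence = "DNAString",
                   topology = "character", features = "data.frame"))

setValidity("GenomeRecord", function(object) {
    msg <- character(0)
    if (!object@topology %in% c("linear", "circular"))
        msg <- c(msg, "topology must be 'linear' or 'circular'")
    n <- length(object@sequence)
    f <- object@features
    need <- c("kind", "start", "end", "strand", "label", "product", "wraps")
    if (!all(need %in% names(f)))
        msg <- c(msg, "features must have columns kind/start/end/strand/label/product/wraps")
    else if (nrow(f) > 0) {
        if (any(f$start < 1 | f$start > n | f$end < 1 | f$end > n))
            msg <- c(msg, "feature coordinates must lie within [1, genome length]")
        bad <- f$start > f$end & !f$wraps
        if (any(bad))
            msg <- c(msg, "non-wrapping features require start <= end")
        if (any(f$wraps) && object@topology != "circular")
            msg <- c(msg, "wrapping features require circular topology")
        if (!all(f$kind %in% .FEATURE_KINDS))
            msg <- c(msg, "feature kind must be CDS, tRNA, gene or other")
        if (!all(f$strand %in% c("+", "-")))
            msg <- c(msg, "feature strand must be '+' or '-'")
    }
    bases <- Biostrings::uniqueLetters(object@sequence)
    if (length(bases) && !all(bases %in% strsplit("ACGTMRWSYKVHDBN", "")[[1]]))
        msg <- c(msg, "sequence contains non-IUPAC letters")
    if (length(msg)) msg else TRUE
})

#' PhysicalMolecule: a duplex DNA molecule with explicit terminal architecture
#'
#' Represents the physical (packaged) form of a linear phage chromosome. The
#' molecule is stored as the top-strand-sense sequence over the union of both
#' strands (\code{unionSeq}); strand coverage is implied by the architecture:
#' \itemize{
#'   \item \code{blunt}: both strands cover the whole union.
#'   \item \code{dtr}: fully duplex; the first and last \code{L} bases of the
#'     union are an identical (double-stranded) terminal repeat.
#'   \item \code{cos_5}: the top strand covers union positions
#'     \code{1..N}, the bottom \code{(L+1)..(N+L)}; both ends carry 5'
#'     single-stranded extensions of length \code{L} that are mutually
#'     cohesive.
#'   \item \code{cos_3}: the mirror arrangement, giving 3' extensions.
#' }
#'
#' @slot unionSeq top-strand-sense \link[Biostrings]{DNAString} over the
#'   union of both strands.
#' @slot architecture one of \code{"blunt"}, \code{"cos_3"}, \code{"cos_5"},
#'   \code{"dtr"}.
#' @slot L overhang / terminal-repeat length in bp (0 for blunt).
#' @exportClass PhysicalMolecule
setClass("PhysicalMolecule",
    representation(unionSeq = "DNAString", architecture = "character",
                   L = "integer"))

setValidity("PhysicalMolecule", function(object) {
    msg <- character(0)
    if (!object@architecture %in% .ARCHITECTURES)
        msg <- c(msg, "architecture must be blunt, cos_3, cos_5 or dtr")
    L <- object@L
    n <- length(object@unionSeq)
    if (length(L) != 1L || is.na(L) || L < 0L)
        msg <- c(msg, "L must be a single non-negative integer")
    else {
        if (object@architecture == "blunt" && L != 0L)
            msg <- c(msg, "blunt molecules require L = 0")
        if (object@architecture != "blunt" && L == 0L)
            msg <- c(msg, "non-blunt architectures require L > 0")
        if (L >= n)
            msg <- c(msg, "L must be smaller than the molecule")
        if (object@architecture == "dtr" && L > 0L) {
            s <- as.character(object@unionSeq)
            if (substr(s, 1L, L) != substr(s, n - L + 1L, n))
                msg <- c(msg, paste("dtr molecules require the terminal",
                                    "repeat at both ends:",
                                    "prefix(L) == suffix(L)"))
        }
    }
    if (length(msg)) msg else TRUE
})

#' TerminalRead: a terminal run-off sequencing read
#'
#' @slot sequence the read as sequenced (5' to 3'); reads from the minus
#'   strand are therefore complementary to the top strand.
#' @slot side \code{"right_end"} (plus-strand read running off the right
#'   physical end) or \code{"left_end"} (minus-strand read running off the
#'   left physical end).
#' @slot primerPos primer coordinate on the template top strand.
#' @slot errorFree logical flag.
#' @exportClass TerminalRead
setClass("TerminalRead",
    representation(sequence = "DNAString", side = "character",
                   primerPos = "integer", errorFree = "logical"))

setValidity("TerminalRead", function(object) {
    if (!object@side %in% c("right_end", "left_end"))
        return("side must be 'right_end' or 'left_end'")
    TRUE
})

#' TerminusCall: classification of a phage genome's terminal architecture
#'
#' @slot category one of \code{"blunt"}, \code{"cos_3"}, \code{"cos_5"},
#'   \code{"dtr"}.
#' @slot L repeat / overhang length (0 for blunt).
#' @slot repeatSeq the terminal repeat (dtr), cohesive overhang (cos), or
#'   \code{""} (blunt).
#' @slot a assembly coordinate of the left physical end.
#' @slot b assembly coordinate of the right physical end.
#' @slot notes free-text diagnostics.
#' @exportClass TerminusCall
setClass("TerminusCall",
    representation(category = "character", L = "integer",
                   repeatSeq = "character", a = "integer", b = "integer",
                   notes = "character"))

setValidity("TerminusCall", function(object) {
    msg <- character(0)
    if (!object@category %in% .ARCHITECTURES)
        msg <- c(msg, "category must be blunt, cos_3, cos_5 or dtr")
    if ((object@category == "blunt") != (object@L == 0L))
        msg <- c(msg, "category blunt iff L == 0")
    if (length(msg)) msg else TRUE
})

#' DNAFragment: a restriction fragment with overhang chemistry
#'
#' Stored as the top-strand-sense sequence over the union of the two strands,
#' plus strand coverage intervals (1-based, relative to \code{unionSeq}).
#'
#' @slot unionSeq top-strand-sense sequence over the fragment's span.
#' @slot topStart,topEnd top-strand coverage within \code{unionSeq}.
#' @slot botStart,botEnd bottom-strand coverage within \code{unionSeq}.
#' @exportClass DNAFragment
setClass("DNAFragment",
    representation(unionSeq = "DNAString", topStart = "integer",
                   topEnd = "integer", botStart = "integer",
                   botEnd = "integer"))

setValidity("DNAFragment", function(object) {
    n <- length(object@unionSeq)
    if (object@topStart < 1L || object@topEnd > n ||
        object@botStart < 1L || object@botEnd > n)
        return("strand coverage must lie within unionSeq")
    if (min(object@topStart, object@botStart) != 1L ||
        max(object@topEnd, object@botEnd) != n)
        return("unionSeq must be exactly the union of the two strands")
    TRUE
})

#' SkewProfile: windowed GC skew with origin prediction
#'
#' @slot window,step window and step sizes in bp.
#' @slot starts window start coordinates (1-based).
#' @slot skew per-window (G-C)/(G+C); windows with G+C = 0 yield 0.
#' @slot cumulative running sum of per-window (G-C) counts normalized by the
#'   total G+C count of the profiled sequence.
#' @slot originEstimate coordinate of the cumulative-skew minimum.
#' @slot originWindowMin coordinate of the per-window skew minimum (reported
#'   for transparency).
#' @exportClass SkewProfile
setClass("SkewProfile",
    representation(window = "integer", step = "integer", starts = "integer",
                   skew = "numeric", cumulative = "numeric",
                   originEstimate = "integer", originWindowMin = "integer"))

setValidity("SkewProfile", function(object) {
    if (length(object@skew) != length(object@starts) ||
        length(object@cumulative) != length(object@starts))
        return("skew, cumulative and starts must have equal length")
    if (length(object@skew) &&
        any(object@skew < -1 - 1e-12 | object@skew > 1 + 1e-12))
        return("skew values must lie in [-1, 1]")
    TRUE
})
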