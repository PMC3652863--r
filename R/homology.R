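#' Genome dotplot: exact shared-word match coordinates
#'
#' Returns the sparse set of coordinates (i, j) at which the \code{word}-mer
#' starting at position i of \code{seqA} equals the word at position j of
#' \code{seqB} (forward channel) or its reverse complement (revcomp channel).
#' Built on a shared k-mer index; the dense matrix is never materialized.
#'
#' @param seqA,seqB DNA sequences (character, DNAString or
#'   \linkS4class{GenomeRecord}).
#' @param word word length in bp (default 9); words shorter than 4 give a
#'   dense matrix and raise a warning.
#' @param revcompChannel also report reverse-complement matches
#'   (default TRUE).
#' @return data.frame \code{i}, \code{j}, \code{channel}
#'   (\code{"forward"} / \code{"revcomp"}).
#' @export
dotplot <- function(seqA, seqB, word = 9L, revcompChannel = TRUE) {
    if (is(seqA, "GenomeRecord")) seqA <- genomeSeq(seqA)
    if (is(seqB, "GenomeRecord")) seqB <- genomeSeq(seqB)
    a <- .asDnaChar(seqA); b <- .asDnaChar(seqB)
    word <- as.integer(word)
    if (nchar(a) < word || nchar(b) < word)
        stop("dotplot: both sequences must be at least `word` long")
    if (word < 4L) warning("word < 4 yields a dense match matrix")
    kmersA <- substring(a, seq_len(nchar(a) - word + 1L),
                        seq_len(nchar(a) - word + 1L) + word - 1L)
    kmersB <- substring(b, seq_len(nchar(b) - word + 1L),
                        seq_len(nchar(b) - word + 1L) + word - 1L)
    idxA <- split(seq_along(kmersA), kmersA)
    match1 <- .kmerJoin(idxA, kmersB)
    out <- if (nrow(match1)) cbind(match1, channel = "forward") else NULL
    if (revcompChannel) {
        rcB <- vapply(kmersB, .revcomp, character(1), USE.NAMES = FALSE)
        match2 <- .kmerJoin(idxA, rcB)
        if (nrow(match2))
            out <- rbind(out, cbind(match2, channel = "revcomp"))
    }
    if (is.null(out))
        out <- data.frame(i = integer(0), j = integer(0),
                          channel = character(0))
    rownames(out) <- NULL
    out
}

.kmerJoin <- function(idxA, kmersB) {
    hitsB <- which(kmersB %in% names(idxA))
    if (!length(hitsB))
        return(data.frame(i = integer(0), j = integer(0)))
    ii <- idxA[kmersB[hitsB]]
    data.frame(i = unlist(ii, use.names = FALSE),
               j = rep(hitsB, lengths(ii)))
}

#' Smith-Waterman local protein alignment score
#'
#' Optimal local alignment raw score under BLOSUM62 with affine gaps
#' (open 11, extend 1), the conventional substitutes for a BLASTP raw score.
#' Symmetric in its arguments; an empty input scores 0.
#'
#' @param a,b amino-acid strings.
#' @param matrix substitution matrix name or matrix (default "BLOSUM62").
#' @param gapOpen,gapExtend affine gap penalties (positive costs).
#' @return alignment score (numeric).
#' @examples
#' localProteinScore("ACDE", "ACDE")  # 24
#' @export
localProteinScore <- function(a, b, matrix = "BLOSUM62", gapOpen = 11,
                              gapExtend = 1) {
    a <- toupper(as.character(a)); b <- toupper(as.character(b))
    if (!nchar(a) || !nchar(b)) return(0)
    if (is.character(matrix)) {
        matName <- matrix
        matrix <- get(data(list = matName, package = "Biostrings",
                           envir = environment()))
    }
    pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
        substitutionMatrix = matrix, gapOpening = gapOpen,
        gapExtension = gapExtend, scoreOnly = TRUE)
    max(pa, 0)
}

# best local score of one query against a set of subjects (vectorized)
.bestScoreAgainst <- function(query, subjects, matrix, gapOpen, gapExtend) {
    subjects <- subjects[nchar(subjects) > 0]
    if (!nchar(query) || !length(subjects)) return(0)
    sc <- Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(subjects), Biostrings::AAString(query),
        type = "local", substitutionMatrix = matrix, gapOpening = gapOpen,
        gapExtension = gapExtend, scoreOnly = TRUE)
    max(sc, 0)
}

#' Core-genome homolog counting across phage proteomes
#'
#' A reference gene is "core" when its best local alignment score against
#' every other proteome reaches \code{threshold} (best-hit semantics, per the
#' CoreGenes convention; the default threshold of 100 mirrors the customary
#' BLASTP score cut-off). Reports the core count and its percentage of the
#' reference proteome size.
#'
#' @param proteomes list (length >= 2) of character vectors of protein
#'   sequences (or \code{AAStringSet}s); names are used in the report.
#' @param threshold minimum qualifying score (default 100).
#' @param reference index of the reference proteome (default 1).
#' @param matrix,gapOpen,gapExtend passed to the aligner.
#' @return list with \code{core_indices}, \code{core_count}, \code{core_pct},
#'   \code{reference_size}, \code{n_proteomes}, and \code{best_scores} (a
#'   matrix of reference genes x other proteomes).
#' @export
coreGenes <- function(proteomes, threshold = 100, reference = 1L,
                      matrix = "BLOSUM62", gapOpen = 11, gapExtend = 1) {
    if (length(proteomes) < 2L) stop("coreGenes: need at least two proteomes")
    proteomes <- lapply(proteomes, function(p) toupper(as.character(p)))
    if (any(vapply(proteomes, length, 1L) == 0L))
        stop("coreGenes: empty proteome")
    if (is.character(matrix)) {
        matName <- matrix
        matrix <- get(data(list = matName, package = "Biostrings",
                           envir = environment()))
    }
    ref <- proteomes[[reference]]
    others <- proteomes[-reference]
    best <- vapply(seq_along(ref), function(g)
        vapply(others, function(p)
            .bestScoreAgainst(ref[g], p, matrix, gapOpen, gapExtend),
            numeric(1)),
        numeric(length(others)))
    best <- matrix(best, nrow = length(others))   # others x ref genes
    isCore <- apply(best >= threshold, 2, all)
    list(core_indices = which(isCore),
         core_count = sum(isCore),
         core_pct = round(100 * sum(isCore) / length(ref), 2),
         reference_size = length(ref),
         n_proteomes = length(proteomes),
         best_scores = t(best))
}
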