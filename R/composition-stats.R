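#' GC content of a DNA sequence
#'
#' Fraction (#G + #C) / (#A + #C + #G + #T): ambiguity codes are excluded
#' from both numerator and denominator.
#'
#' @param x a \linkS4class{GenomeRecord}, \link[Biostrings]{DNAString} or
#'   character sequence.
#' @return a fraction in [0, 1].
#' @examples
#' gcContent("GGCC")  # 1
#' gcContent("ATAT")  # 0
#' @export
gcContent <- function(x) {
    if (is(x, "GenomeRecord")) x <- genomeSeq(x)
    s <- Biostrings::DNAString(.asDnaChar(x))
    if (length(s) == 0L) stop("gcContent: empty sequence")
    counts <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
    unambig <- sum(counts)
    if (unambig == 0L) stop("gcContent: no unambiguous bases")
    unname((counts[["G"]] + counts[["C"]]) / unambig)
}

#' Annotation statistics: coding density and gene-length summaries
#'
#' Coding bases are the union of all CDS and tRNA feature intervals (genes
#' overlapping each other are not double counted); non-coding percentage is
#' \code{100 * (1 - coding/N)} rounded to one decimal. Mean CDS length is
#' reported both as the mean feature span (default, \code{mean_cds_len}) and
#' as coding-union bp over the CDS count (\code{mean_cds_len_union}).
#'
#' @param record a \linkS4class{GenomeRecord}.
#' @return a one-row data.frame with columns \code{n_genes}, \code{n_cds},
#'   \code{n_trna}, \code{coding_bp}, \code{noncoding_pct},
#'   \code{mean_cds_len}, \code{mean_cds_len_union}.
#' @export
annotationStats <- function(record) {
    stopifnot(is(record, "GenomeRecord"))
    n <- length(record)
    f <- featureTable(record)
    cod <- f[f$kind %in% c("CDS", "tRNA"), , drop = FALSE]
    coding_bp <- 0L
    if (nrow(cod)) {
        # unwrap circular features into linear pieces before taking the union
        starts <- ends <- integer(0)
        for (k in seq_len(nrow(cod))) {
            if (cod$wraps[k]) {
                starts <- c(starts, cod$start[k], 1L)
                ends <- c(ends, n, cod$end[k])
            } else {
                starts <- c(starts, cod$start[k])
                ends <- c(ends, cod$end[k])
            }
        }
        coding_bp <- sum(IRanges::width(IRanges::reduce(
            IRanges::IRanges(start = starts, end = ends))))
    }
    cds <- cod[cod$kind == "CDS", , drop = FALSE]
    spans <- .featureSpan(cds, n)
    data.frame(
        n_genes = nrow(cod),
        n_cds = nrow(cds),
        n_trna = sum(cod$kind == "tRNA"),
        coding_bp = coding_bp,
        noncoding_pct = round(100 * (1 - coding_bp / n), 1),
        mean_cds_len = if (nrow(cds)) round(mean(spans)) else NA_integer_,
        mean_cds_len_union = if (nrow(cds)) round(coding_bp / nrow(cds))
                             else NA_integer_)
}

#' Extract the strand-resolved sequence of a feature
#' @param record a \linkS4class{GenomeRecord}.
#' @param feature a one-row slice of \code{featureTable(record)}.
#' @return character sequence, 5' to 3' on the coding strand.
#' @export
featureSeq <- function(record, feature) {
    s <- as.character(genomeSeq(record))
    sub <- if (isTRUE(feature$wraps)) {
        if (topology(record) != "circular")
            stop("wrapping feature on a linear record")
        .circArc(s, feature$start, feature$end)
    } else substr(s, feature$start, feature$end)
    if (feature$strand == "-") .revcomp(sub) else sub
}

#' Translate a CDS feature
#'
#' Strand-resolves the feature sequence and translates it with the standard
#' genetic code (or another \code{GENETIC_CODE}-style table), removing the
#' terminal stop. Internal stop codons raise a warning naming the first
#' offending codon position; a span not divisible by 3 is an error.
#'
#' @param record a \linkS4class{GenomeRecord}.
#' @param feature a one-row slice of \code{featureTable(record)} with
#'   \code{kind == "CDS"}.
#' @param geneticCode a named character vector in the format of
#'   \link[Biostrings]{GENETIC_CODE}.
#' @return the protein as a character string.
#' @examples
#' gr <- GenomeRecord("ATGAAATAA",
#'   features = data.frame(kind = "CDS", start = 1, end = 9, strand = "+"))
#' translateCds(gr, featureTable(gr)[1, ])  # "MK"
#' @export
translateCds <- function(record, feature,
                         geneticCode = Biostrings::GENETIC_CODE) {
    if (feature$kind != "CDS") stop("translateCds: feature is not a CDS")
    nt <- featureSeq(record, feature)
    if (nchar(nt) %% 3L != 0L)
        stop("translateCds: CDS length ", nchar(nt), " not divisible by 3")
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                             genetic.code = geneticCode,
                                             if.fuzzy.codon = "X"))
    ncod <- nchar(aa)
    if (substr(aa, ncod, ncod) == "*") aa <- substr(aa, 1L, ncod - 1L)
    stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
    if (stops[1] != -1L)
        warning("internal stop codon at codon ", stops[1], " of '",
                feature$label, "'")
    aa
}

# Expasy-style average and monoisotopic residue masses (Da)
.AA_AVG <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
             C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519,
             H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741,
             M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782,
             T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.AA_MONO <- c(A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694,
              C = 103.00919, E = 129.04259, Q = 128.05858, G = 57.02146,
              H = 137.05891, I = 113.08406, L = 113.08406, K = 128.09496,
              M = 131.04049, F = 147.06841, P = 97.05276, S = 87.03203,
              T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841)
.WATER_AVG <- 18.01524
.WATER_MONO <- 18.010565

#' Theoretical protein molecular weight
#'
#' Sum of residue masses plus one water, in kDa rounded to two decimals.
#' Average (Expasy-style) masses are the default, matching the convention of
#' theoretically calculated phage protein weights; monoisotopic masses are
#' available behind \code{monoisotopic = TRUE}.
#'
#' @param protein amino-acid string over the standard 20-letter alphabet.
#' @param monoisotopic use monoisotopic residue masses.
#' @param kDa return kilodaltons rounded to 2 decimals (default); otherwise
#'   daltons at full precision.
#' @return numeric mass.
#' @examples
#' proteinMw("GG")  # 0.13
#' @export
proteinMw <- function(protein, monoisotopic = FALSE, kDa = TRUE) {
    aa <- strsplit(toupper(protein), "")[[1]]
    tab <- if (monoisotopic) .AA_MONO else .AA_AVG
    bad <- setdiff(unique(aa), names(tab))
    if (length(bad))
        stop("proteinMw: unknown amino acid letter(s): ",
             paste(bad, collapse = ", "))
    water <- if (monoisotopic) .WATER_MONO else .WATER_AVG
    da <- sum(tab[aa]) + water
    if (kDa) round(da / 1000, 2) else da
}
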