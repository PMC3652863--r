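.AA3TO1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Glu = "E", Gln = "Q", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

#' Codon usage and RSCU from a set of in-frame CDS sequences
#'
#' Counts all codons across the supplied coding sequences and computes
#' per-1000 frequencies and the relative synonymous codon usage,
#' RSCU = observed / (family total / family size). Stop codons are excluded
#' by default. Within every synonymous family with nonzero counts the mean
#' RSCU is 1 by construction.
#'
#' @param cdsList character vector (or \link[Biostrings]{DNAStringSet}) of
#'   in-frame CDS sequences; each length must be divisible by 3.
#' @param excludeStops drop stop codons from the table (default TRUE).
#' @param label source label, e.g. \code{"phage"} or \code{"host"}.
#' @return data.frame \code{codon}, \code{aa}, \code{count}, \code{per_1000},
#'   \code{rscu} (one row per codon), with attribute \code{source}.
#' @examples
#' cu <- codonUsage("ATGAAAAAATAA")
#' cu[cu$codon == "AAA", ]  # count 2, RSCU 2
#' @export
codonUsage <- function(cdsList, excludeStops = TRUE, label = "phage") {
    cdsList <- .asDnaChar(cdsList)
    counts <- setNames(integer(length(Biostrings::GENETIC_CODE)),
                       names(Biostrings::GENETIC_CODE))
    for (i in seq_along(cdsList)) {
        s <- cdsList[i]
        if (nchar(s) %% 3L != 0L)
            stop("codonUsage: CDS ", i, " has length ", nchar(s),
                 ", not divisible by 3")
        codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
        tab <- table(codons)
        known <- intersect(names(tab), names(counts))
        counts[known] <- counts[known] + as.integer(tab[known])
    }
    aa <- Biostrings::GENETIC_CODE[names(counts)]
    df <- data.frame(codon = names(counts), aa = unname(aa),
                     count = unname(counts), stringsAsFactors = FALSE)
    if (excludeStops) df <- df[df$aa != "*", , drop = FALSE]
    total <- sum(df$count)
    df$per_1000 <- if (total > 0) 1000 * df$count / total else 0
    famTotal <- tapply(df$count, df$aa, sum)[df$aa]
    famSize <- tapply(df$count, df$aa, length)[df$aa]
    df$rscu <- as.numeric(ifelse(famTotal > 0,
                                 df$count / (famTotal / famSize), NA_real_))
    rownames(df) <- NULL
    attr(df, "source") <- label
    df
}

.resolveTrnaCodons <- function(aminoAcid, anticodon, codonTable) {
    if (!is.na(anticodon) && nzchar(anticodon))
        return(.revcomp(anticodon))
    a1 <- if (aminoAcid %in% names(.AA3TO1)) .AA3TO1[[aminoAcid]]
          else toupper(aminoAcid)
    codonTable$codon[codonTable$aa == a1]
}

#' Phage-versus-host tRNA advantage
#'
#' For each phage-encoded tRNA, compares how often the codons it decodes are
#' used by the phage versus by its host: the usage ratio
#' \code{r = phage per-1000 frequency / host per-1000 frequency} over the
#' decoded codons. Entries with \code{r >= flagRatio} are flagged as codons
#' the phage uses preferentially -- the rationale for a phage carrying its
#' own tRNA genes despite relying on the host translation machinery.
#'
#' @param phage,host codon usage tables from \code{\link{codonUsage}}.
#' @param phageTrnas data.frame with column \code{amino_acid} (three-letter,
#'   e.g. "Arg", or one-letter codes) and optional \code{anticodon}; or a
#'   character vector of amino acids.
#' @param flagRatio ratio at or above which an entry is flagged
#'   (default 1.5).
#' @return data.frame \code{amino_acid}, \code{codons}, \code{phage_per1000},
#'   \code{host_per1000}, \code{ratio}, \code{flagged}, ordered by ratio
#'   descending.
#' @export
trnaAdvantage <- function(phage, host, phageTrnas, flagRatio = 1.5) {
    if (!nrow(phage) || !nrow(host))
        stop("trnaAdvantage: empty codon usage table")
    if (is.character(phageTrnas))
        phageTrnas <- data.frame(amino_acid = phageTrnas,
                                 stringsAsFactors = FALSE)
    if (is.null(phageTrnas$anticodon)) phageTrnas$anticodon <- NA_character_
    rows <- lapply(seq_len(nrow(phageTrnas)), function(i) {
        aaName <- phageTrnas$amino_acid[i]
        codons <- .resolveTrnaCodons(aaName, phageTrnas$anticodon[i], phage)
        pf <- sum(phage$per_1000[phage$codon %in% codons])
        hf <- sum(host$per_1000[host$codon %in% codons])
        if (pf == 0 && hf == 0)
            warning("tRNA for ", aaName,
                    ": decoded codons absent from both tables")
        data.frame(amino_acid = aaName,
                   codons = paste(codons, collapse = ","),
                   phage_per1000 = pf, host_per1000 = hf,
                   ratio = if (hf > 0) pf / hf else if (pf > 0) Inf else NA,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$flagged <- !is.na(out$ratio) & out$ratio >= flagRatio
    out[order(-out$ratio), , drop = FALSE]
}
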