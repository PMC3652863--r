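#' Built-in restriction enzyme table
#'
#' Ships the three enzymes used for phage terminal-fragment release: NarI
#' (GG^CGCC), NotI (GC^GGCCGC) and FspI (TGC^GCA, blunt). \code{cut_top} and
#' \code{cut_bottom} are offsets from the recognition start on top-strand
#' coordinates; only within-site cutters are supported. Extend with
#' \code{\link{readEnzymes}}.
#'
#' @return data.frame with columns \code{name}, \code{recognition},
#'   \code{cut_top}, \code{cut_bottom}.
#' @export
builtinEnzymes <- function() {
    data.frame(name = c("NarI", "NotI", "FspI"),
               recognition = c("GGCGCC", "GCGGCCGC", "TGCGCA"),
               cut_top = c(2L, 2L, 3L),
               cut_bottom = c(4L, 6L, 3L),
               stringsAsFactors = FALSE)
}

#' Read a restriction-enzyme definition TSV
#'
#' Columns: name, recognition (IUPAC), cut_top, cut_bottom.
#' @param path TSV path.
#' @return enzyme data.frame as in \code{\link{builtinEnzymes}}.
#' @export
readEnzymes <- function(path) {
    db <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("name", "recognition", "cut_top", "cut_bottom")
    if (!all(need %in% names(db)))
        stop("enzyme TSV must have columns: ", paste(need, collapse = ", "))
    db$recognition <- toupper(db$recognition)
    db$cut_top <- as.integer(db$cut_top)
    db$cut_bottom <- as.integer(db$cut_bottom)
    bad <- db$cut_top < 0 | db$cut_top > nchar(db$recognition) |
           db$cut_bottom < 0 | db$cut_bottom > nchar(db$recognition)
    if (any(bad))
        stop("within-site cutters only: offsets out of range for ",
             paste(db$name[bad], collapse = ", "))
    db
}

.isPalindromic <- function(recognition) {
    recognition == paste(rev(strsplit(.comp(recognition), "")[[1]]),
                         collapse = "")
}

# degenerate IUPAC matches of `pattern` in `subject` (character), top strand,
# ambiguity codes in the subject treated as non-match
.iupacMatches <- function(pattern, subject) {
    hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject),
                                     fixed = "subject")
    BiocGenerics::start(hits)
}

#' Find restriction sites on a genome record
#'
#' Scans the double-stranded molecule for the enzyme's (possibly degenerate)
#' recognition sequence. Palindromic recognitions are reported once per
#' locus; non-palindromic recognitions are also searched on the bottom strand
#' (reported at their top-strand start with \code{strand = "-"}). Circular
#' topology scans across the origin.
#'
#' @param record a \linkS4class{GenomeRecord}.
#' @param enzyme one row of an enzyme data.frame
#'   (see \code{\link{builtinEnzymes}}).
#' @return data.frame of cut sites: \code{enzyme}, \code{position}
#'   (recognition start, 1-based), \code{strand}, \code{cut_top_after},
#'   \code{cut_bottom_after} (the top/bottom strand is cut after this
#'   top-strand coordinate), sorted by position.
#' @examples
#' rec <- GenomeRecord("TTGGCGCCTT")
#' findSites(rec, builtinEnzymes()[1, ])  # NarI at position 3
#' @export
findSites <- function(record, enzyme) {
    stopifnot(is(record, "GenomeRecord"))
    s <- as.character(genomeSeq(record))
    n <- nchar(s)
    m <- nchar(enzyme$recognition)
    circular <- topology(record) == "circular"
    subject <- if (circular) paste0(s, substr(s, 1L, m - 1L)) else s
    clip <- function(p) p[p <= n]
    pos <- .iupacMatches(enzyme$recognition, subject)
    if (circular) pos <- clip(pos)
    sites <- data.frame(enzyme = rep(enzyme$name, length(pos)),
                        position = pos, strand = rep("+", length(pos)),
                        cut_top_after = pos + enzyme$cut_top - 1L,
                        cut_bottom_after = pos + enzyme$cut_bottom - 1L,
                        stringsAsFactors = FALSE)
    if (!.isPalindromic(enzyme$recognition)) {
        rcpat <- .revcomp(enzyme$recognition)
        pos2 <- .iupacMatches(rcpat, subject)
        if (circular) pos2 <- clip(pos2)
        pos2 <- setdiff(pos2, pos)   # degenerate self-overlap safety
        if (length(pos2)) {
            sites <- rbind(sites, data.frame(
                enzyme = rep(enzyme$name, length(pos2)),
                position = pos2, strand = rep("-", length(pos2)),
                cut_top_after = pos2 + m - enzyme$cut_bottom - 1L,
                cut_bottom_after = pos2 + m - enzyme$cut_top - 1L,
                stringsAsFactors = FALSE))
        }
    }
    sites[order(sites$position), , drop = FALSE]
}

#' Select enzymes with exactly one recognition site
#'
#' The paper-style filter for choosing enzymes that release unique terminal
#' fragments from a genome.
#'
#' @param record a \linkS4class{GenomeRecord}.
#' @param enzymeDb enzyme data.frame (default \code{\link{builtinEnzymes}}).
#' @return data.frame \code{name}, \code{position}, alphabetically sorted by
#'   name; zero rows if none qualify.
#' @export
singleCutters <- function(record, enzymeDb = builtinEnzymes()) {
    if (nrow(enzymeDb) == 0)
        return(data.frame(name = character(0), position = integer(0)))
    out <- do.call(rbind, lapply(seq_len(nrow(enzymeDb)), function(i) {
        sites <- findSites(record, enzymeDb[i, ])
        if (nrow(sites) == 1L)
            data.frame(name = enzymeDb$name[i], position = sites$position,
                       stringsAsFactors = FALSE)
        else NULL
    }))
    if (is.null(out))
        return(data.frame(name = character(0), position = integer(0)))
    out[order(out$name), , drop = FALSE]
}

# ---- duplex representation helpers -----------------------------------------
# a "duplex" is list(u = union top-sense char, t1, t2, b1, b2)

.moleculeDuplex <- function(x) {
    u <- as.character(x@unionSeq)
    n <- nchar(u)
    L <- x@L
    switch(x@architecture,
        blunt = ,
        dtr = list(u = u, t1 = 1L, t2 = n, b1 = 1L, b2 = n),
        cos_5 = list(u = u, t1 = 1L, t2 = n - L, b1 = L + 1L, b2 = n),
        cos_3 = list(u = u, t1 = L + 1L, t2 = n, b1 = 1L, b2 = n - L))
}

.fragmentFromDuplex <- function(d) {
    new("DNAFragment", unionSeq = Biostrings::DNAString(d$u),
        topStart = as.integer(d$t1), topEnd = as.integer(d$t2),
        botStart = as.integer(d$b1), botEnd = as.integer(d$b2))
}

# digest a linear duplex at given cut coordinates (union coords);
# cuts: data.frame(cut_top_after, cut_bottom_after), assumed within duplex
.digestDuplex <- function(d, cuts) {
    if (nrow(cuts) == 0L) return(list(.fragmentFromDuplex(d)))
    cuts <- cuts[order(cuts$cut_top_after), , drop = FALSE]
    tb <- c(d$t1 - 1L, cuts$cut_top_after, d$t2)
    bb <- c(d$b1 - 1L, cuts$cut_bottom_after, d$b2)
    frags <- vector("list", nrow(cuts) + 1L)
    for (k in seq_along(frags)) {
        tS <- tb[k] + 1L; tE <- tb[k + 1L]
        bS <- bb[k] + 1L; bE <- bb[k + 1L]
        uS <- min(tS, bS); uE <- max(tE, bE)
        frags[[k]] <- new("DNAFragment",
            unionSeq = Biostrings::DNAString(substr(d$u, uS, uE)),
            topStart = tS - uS + 1L, topEnd = tE - uS + 1L,
            botStart = bS - uS + 1L, botEnd = bE - uS + 1L)
    }
    frags
}

# cut events fully inside the duplex region of `d` for an enzyme set
.duplexCuts <- function(d, enzymes) {
    n <- nchar(d$u)
    dupS <- max(d$t1, d$b1); dupE <- min(d$t2, d$b2)
    rec <- GenomeRecord(d$u)
    out <- list()
    for (i in seq_len(nrow(enzymes))) {
        sites <- findSites(rec, enzymes[i, ])
        m <- nchar(enzymes$recognition[i])
        keep <- sites$position >= dupS & sites$position + m - 1L <= dupE &
                sites$cut_top_after >= dupS & sites$cut_top_after < dupE &
                sites$cut_bottom_after >= dupS & sites$cut_bottom_after < dupE
        out[[i]] <- sites[keep, c("cut_top_after", "cut_bottom_after")]
    }
    cuts <- do.call(rbind, out)
    unique(cuts[order(cuts$cut_top_after), , drop = FALSE])
}

#' Simulate a restriction digest
#'
#' Cuts a genome record (linear or circular) or a physical molecule with one
#' or more enzymes and returns the resulting fragments in left-to-right order
#' (circular digests start at the first cut; a circular molecule with no cut
#' site is returned intact as a single fragment). Fragment ends carry the
#' overhang chemistry implied by the enzyme's cut offsets; recognition sites
#' falling in single-stranded terminal regions are not cut.
#'
#' @param molecule a \linkS4class{GenomeRecord} or
#'   \linkS4class{PhysicalMolecule}.
#' @param enzymes enzyme data.frame (one or more rows).
#' @return list of \linkS4class{DNAFragment}.
#' @seealso \code{\link{fragmentTable}} for a TSV-ready summary.
#' @export
digest <- function(molecule, enzymes) {
    if (nrow(enzymes) == 0L) stop("digest: need at least one enzyme")
    if (is(molecule, "PhysicalMolecule")) {
        d <- .moleculeDuplex(molecule)
        return(.digestDuplex(d, .duplexCuts(d, enzymes)))
    }
    stopifnot(is(molecule, "GenomeRecord"))
    s <- as.character(genomeSeq(molecule))
    n <- nchar(s)
    if (n == 0L) stop("digest: empty molecule")
    if (topology(molecule) == "linear") {
        d <- list(u = s, t1 = 1L, t2 = n, b1 = 1L, b2 = n)
        return(.digestDuplex(d, .duplexCuts(d, enzymes)))
    }
    # circular: locate all cuts on the circle, linearize at the first cut
    allSites <- do.call(rbind, lapply(seq_len(nrow(enzymes)), function(i)
        findSites(molecule, enzymes[i, ])))
    if (is.null(allSites) || nrow(allSites) == 0L) {
        d <- list(u = s, t1 = 1L, t2 = n, b1 = 1L, b2 = n)
        return(list(.fragmentFromDuplex(d)))
    }
    allSites <- allSites[order(allSites$cut_top_after), , drop = FALSE]
    tc1 <- .circIdx(allSites$cut_top_after[1L], n)
    bc1 <- allSites$cut_bottom_after[1L] - allSites$cut_top_after[1L] + tc1
    dd <- bc1 - tc1                       # bottom lag (5' overhang if > 0)
    span <- n + abs(dd)
    rot <- .rotateSeq(s, min(tc1, bc1) + 1L)
    u <- substr(paste0(rot, rot), 1L, span)
    if (dd >= 0L) d <- list(u = u, t1 = 1L, t2 = n, b1 = dd + 1L, b2 = dd + n)
    else d <- list(u = u, t1 = -dd + 1L, t2 = -dd + n, b1 = 1L, b2 = n)
    .digestDuplex(d, .duplexCuts(d, enzymes))
}

#' Summarize digest fragments as a table
#'
#' One row per fragment: index, length of the longest strand, and overhang
#' sequence/polarity at each end. Sorted fragment lengths stand in for gel
#' "bands".
#'
#' @param fragments list of \linkS4class{DNAFragment} from
#'   \code{\link{digest}}.
#' @return data.frame.
#' @export
fragmentTable <- function(fragments) {
    do.call(rbind, lapply(seq_along(fragments), function(i) {
        f <- fragments[[i]]
        lo <- leftOverhang(f); ro <- rightOverhang(f)
        data.frame(fragment = i, length = fragmentLength(f),
                   left_overhang = lo$sequence, left_polarity = lo$polarity,
                   right_overhang = ro$sequence, right_polarity = ro$polarity,
                   stringsAsFactors = FALSE)
    }))
}

#' @rdname DNAFragment-class
#' @aliases fragmentLength leftOverhang rightOverhang
#' @export
setMethod("fragmentLength", "DNAFragment", function(x)
    max(x@topEnd - x@topStart + 1L, x@botEnd - x@botStart + 1L))

#' @rdname DNAFragment-class
#' @export
setMethod("leftOverhang", "DNAFragment", function(x) {
    u <- as.character(x@unionSeq)
    if (x@topStart < x@botStart)          # top strand protrudes: 5' end
        list(sequence = substr(u, x@topStart, x@botStart - 1L),
             polarity = "5'")
    else if (x@botStart < x@topStart)     # bottom strand protrudes: its 3' end
        list(sequence = .revcomp(substr(u, x@botStart, x@topStart - 1L)),
             polarity = "3'")
    else list(sequence = "", polarity = "none")
})

#' @rdname DNAFragment-class
#' @export
setMethod("rightOverhang", "DNAFragment", function(x) {
    u <- as.character(x@unionSeq)
    if (x@topEnd > x@botEnd)              # top strand protrudes: its 3' end
        list(sequence = substr(u, x@botEnd + 1L, x@topEnd), polarity = "3'")
    else if (x@botEnd > x@topEnd)         # bottom strand protrudes: its 5' end
        list(sequence = .revcomp(substr(u, x@topEnd + 1L, x@botEnd)),
             polarity = "5'")
    else list(sequence = "", polarity = "none")
})

setMethod("show", "DNAFragment", function(object) {
    lo <- leftOverhang(object); ro <- rightOverhang(object)
    cat(sprintf("DNAFragment: %d nt (left: %s %s | right: %s %s)\n",
                fragmentLength(object), lo$polarity, lo$sequence,
                ro$polarity, ro$sequence))
})

#' @rdname s1Trim
#' @export
setMethod("s1Trim", "DNAFragment", function(x) {
    u <- as.character(x@unionSeq)
    s <- max(x@topStart, x@botStart); e <- min(x@topEnd, x@botEnd)
    new("DNAFragment", unionSeq = Biostrings::DNAString(substr(u, s, e)),
        topStart = 1L, topEnd = e - s + 1L, botStart = 1L,
        botEnd = e - s + 1L)
})
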