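#' Specification for a synthetic phage genome with planted ground truth
#'
#' The defaults emulate the PaP1-like study configuration: a 91,715 bp genome
#' at GC 0.4936 with a 1190 bp terminal redundancy, 157 CDS of mean span
#' 504 bp plus 12 tRNA genes laid out to leave 13.8\% of the genome
#' non-coding, one NarI (GGCGCC) site about 2.5 kb from the left physical end
#' and one NotI (GCGGCCGC) site about 6.5 kb from the right physical end, and
#' a GC-skew switch (replication origin) near the end of the unit sequence.
#'
#' @param length genome (assembly unit) length N in bp.
#' @param gcTarget target GC fraction.
#' @param architecture terminal architecture: \code{"blunt"}, \code{"cos_3"},
#'   \code{"cos_5"} or \code{"dtr"}.
#' @param L overhang / terminal-repeat length (bp; 0 for blunt).
#' @param plantedSites data.frame with columns \code{recognition} and
#'   \code{position} (approximate; each recognition is made to occur exactly
#'   once on the circle), or NULL.
#' @param nCds,meanCdsLen,nTrna,trnaLen planted gene content (counts, bp).
#' @param noncodingPct target non-coding percentage of the genome; small
#'   inter-gene overlaps are introduced when the gene content alone would
#'   exceed the coding target.
#' @param skewSwitch coordinate of the planted GC-skew sign switch (the
#'   planted replication origin), or NULL for no skew structure.
#' @param skewAmplitude GC-skew amplitude on each replichore arm
#'   (default 0.1).
#' @param seed integer seed; identical spec + seed give byte-identical
#'   output.
#' @return a list of class \code{"SyntheticGenomeSpec"}.
#' @export
syntheticGenomeSpec <- function(length = 91715L, gcTarget = 0.4936,
                                architecture = "dtr", L = 1190L,
                                plantedSites = data.frame(
                                    recognition = c("GGCGCC", "GCGGCCGC"),
                                    position = c(2500L, 86405L),
                                    stringsAsFactors = FALSE),
                                nCds = 157L, meanCdsLen = 504L,
                                nTrna = 12L, trnaLen = 76L,
                                noncodingPct = 13.8,
                                skewSwitch = round(0.98 * length),
                                skewAmplitude = 0.1, seed = 1L) {
    spec <- list(length = as.integer(length), gcTarget = gcTarget,
                 architecture = architecture, L = as.integer(L),
                 plantedSites = plantedSites, nCds = as.integer(nCds),
                 meanCdsLen = as.integer(meanCdsLen), nTrna = as.integer(nTrna),
                 trnaLen = as.integer(trnaLen), noncodingPct = noncodingPct,
                 skewSwitch = if (is.null(skewSwitch)) NULL
                              else as.integer(skewSwitch),
                 skewAmplitude = skewAmplitude, seed = as.integer(seed))
    stopifnot(spec$architecture %in% .ARCHITECTURES,
              spec$L >= 0L, spec$L < spec$length %/% 2L,
              (spec$architecture == "blunt") == (spec$L == 0L),
              spec$gcTarget > 0, spec$gcTarget < 1)
    class(spec) <- "SyntheticGenomeSpec"
    spec
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

# draw CDS spans (multiples of 3) with an exact target mean
.drawCdsSpans <- function(n, meanLen) {
    if (n == 0L) return(integer(0))
    spans <- 3L * pmax(40L, round(rnorm(n, meanLen / 3, 17)))
    target <- n * meanLen - (n * meanLen) %% 3L  # keep multiples of 3 tidy
    target <- n * meanLen
    i <- 1L
    while (sum(spans) != target) {
        d <- target - sum(spans)
        stepv <- if (d > 0) 3L else -3L
        k <- sample.int(n, 1L)
        if (spans[k] + stepv >= 120L &&
            abs(d) >= 3L) spans[k] <- spans[k] + stepv
        else if (abs(d) < 3L) {
            # meanLen * n not divisible by 3: absorb remainder in one span
            spans[k] <- spans[k] + d
            break
        }
        i <- i + 1L
        if (i > 100000L) stop("could not balance CDS spans")
    }
    spans
}

# distribute `total` non-negative integer gaps over m junctions
.splitGaps <- function(total, m) {
    if (m == 0L) return(integer(0))
    if (total <= 0L) return(integer(m))
    w <- runif(m)
    g <- floor(total * w / sum(w))
    g[1L] <- g[1L] + total - sum(g)
    as.integer(g)
}

.layoutFeatures <- function(spec) {
    nFeat <- spec$nCds + spec$nTrna
    if (nFeat == 0L)
        return(.emptyFeatures())
    spans <- c(.drawCdsSpans(spec$nCds, spec$meanCdsLen),
               rep(spec$trnaLen, spec$nTrna))
    kinds <- c(rep("CDS", spec$nCds), rep("tRNA", spec$nTrna))
    ord <- sample.int(nFeat)
    spans <- spans[ord]; kinds <- kinds[ord]
    N <- spec$length
    S <- sum(spans)
    G <- N - S                                  # signed gap budget
    if (G < 0L)
        stop("infeasible spec: planted genes exceed the genome length")
    NC <- round(N * spec$noncodingPct / 100)
    Q <- max(0L, as.integer(NC - G))            # total overlap needed
    # overlap sizes avoid multiples of 3 (a same-strand in-frame overlap
    # would force one gene's terminal stop into the other's reading frame)
    # and stay >= 7 so the two genes' fixed start/stop codons at a junction
    # never share a base (codon collisions at 4-5 bp overlaps are
    # unsatisfiable for some strand combinations)
    sizes <- c(7L, 8L, 10L, 11L)
    finish <- list(`7` = 7L, `8` = 8L, `10` = 10L, `11` = 11L,
                   `14` = c(7L, 7L), `15` = c(7L, 8L), `16` = c(8L, 8L),
                   `17` = c(7L, 10L), `18` = c(7L, 11L), `19` = c(8L, 11L),
                   `20` = c(10L, 10L), `21` = c(10L, 11L), `22` = c(11L, 11L))
    overlaps <- integer(0)
    rem <- Q
    while (rem > 22L) {
        s <- sample(sizes, 1L)
        # keep the remainder representable (>= 14 or a single size)
        if (!(rem - s >= 14L || (rem - s) %in% sizes)) next
        overlaps <- c(overlaps, s)
        rem <- rem - s
    }
    if (rem > 0L) {
        tail <- finish[[as.character(rem)]]
        if (is.null(tail))
            stop("infeasible spec: overlap budget of ", Q, " bp cannot be ",
                 "decomposed into frame-shifting overlap sizes")
        overlaps <- c(overlaps, tail)
    }
    if (length(overlaps) >= nFeat)
        stop("infeasible spec: non-coding target requires too many overlaps")
    P <- G + sum(overlaps)                      # positive gap budget
    mPos <- nFeat - length(overlaps)
    # junction nFeat (closing the circle) must stay non-negative: keep a
    # positive gap in the last slot and shuffle the rest
    gaps <- c(-overlaps, .splitGaps(as.integer(P), mPos))
    idx <- sample.int(length(gaps) - 1L)
    gaps <- c(gaps[idx], gaps[length(gaps)])
    cursor <- 1L
    start <- end <- integer(nFeat)
    for (i in seq_len(nFeat)) {
        start[i] <- cursor
        end[i] <- cursor + spans[i] - 1L
        cursor <- end[i] + 1L + gaps[i]
    }
    if (cursor != N + 1L) stop("internal layout error")
    labels <- sprintf("g%03d", seq_len(nFeat))
    data.frame(kind = kinds, start = start, end = end,
               strand = sample(c("+", "-"), nFeat, replace = TRUE),
               label = labels,
               product = ifelse(kinds == "CDS", "hypothetical protein",
                                "tRNA"),
               wraps = FALSE, stringsAsFactors = FALSE)
}

# genome positions of every CDS's fixed codons (start + terminal): the
# first and last 3 bases of each span, whatever the strand
.fixedCodonPositions <- function(features) {
    cds <- features[features$kind == "CDS", , drop = FALSE]
    if (!nrow(cds)) return(integer(0))
    unique(c(unlist(lapply(seq_len(nrow(cds)), function(i)
        c(cds$start[i]:(cds$start[i] + 2L),
          (cds$end[i] - 2L):cds$end[i])))))
}

# ensure each CDS has ATG start, terminal stop, and (best effort) no
# internal stops; edits the top-strand char vector in place. Internal-stop
# edits avoid other genes' fixed codons (the consistency-aware repair pass
# deals with those afterwards).
.carveCds <- function(chars, features) {
    cds <- features[features$kind == "CDS", , drop = FALSE]
    fixedPos <- .fixedCodonPositions(features)
    for (i in seq_len(nrow(cds))) {
        idx <- cds$start[i]:cds$end[i]
        if (cds$strand[i] == "-") idx <- rev(idx)
        seqc <- chars[idx]
        if (cds$strand[i] == "-") seqc <- .compChars(seqc)
        ncod <- length(seqc) %/% 3L
        seqc[1:3] <- c("A", "T", "G")
        seqc[(3 * ncod - 2):(3 * ncod)] <- strsplit(
            sample(.STOP_CODONS, 1L), "")[[1]]
        ownFixed <- c(idx[1:3], idx[(3 * ncod - 2):(3 * ncod)])
        if (ncod > 2L) {
            for (k in 2:(ncod - 1L)) {
                cod <- paste(seqc[(3 * k - 2):(3 * k)], collapse = "")
                # GC-neutral third-base edits: TAA->TAT, TAG->TAC, TGA->TGT
                if (cod %in% .STOP_CODONS &&
                    !(idx[3 * k] %in% setdiff(fixedPos, ownFixed)))
                    seqc[3 * k] <- switch(cod, TAA = "T", TAG = "C",
                                          TGA = "T")
            }
        }
        if (cds$strand[i] == "-") seqc <- .compChars(seqc)
        chars[idx] <- seqc
    }
    chars
}

.compChars <- function(x) unname(c(A = "T", C = "G", G = "C", T = "A")[x])

# the codon of CDS row `r` (in a features table) containing circle position
# `pos`, under the base vector `chars`: list(codon, k, ncod), k 0-based
.codonAt <- function(chars, r, pos) {
    idx <- r$start:r$end
    if (r$strand == "-") idx <- rev(idx)
    seqc <- chars[idx]
    if (r$strand == "-") seqc <- .compChars(seqc)
    off <- which(idx == pos)
    k <- (off - 1L) %/% 3L
    list(codon = paste(seqc[(3 * k + 1):(3 * k + 3)], collapse = ""),
         k = k, ncod = length(seqc) %/% 3L)
}

# a base substitution at `pos` consistent with every covering CDS frame:
# start codon stays ATG, terminal codon stays a stop, internal codons stay
# non-stop. Returns the new base, or NA when no substitution qualifies.
.consistentSubstitution <- function(chars, pos, features) {
    cds <- features[features$kind == "CDS", , drop = FALSE]
    covering <- which(cds$start <= pos & cds$end >= pos)
    # GC-preserving swap first (A<->T, C<->G) to protect the GC target
    cur <- chars[pos]
    neutral <- c(A = "T", T = "A", C = "G", G = "C")[[cur]]
    cand <- c(neutral, setdiff(c("A", "C", "G", "T"), c(cur, neutral)))
    for (b in cand) {
        trial <- chars
        trial[pos] <- b
        ok <- TRUE
        for (ci in covering) {
            ca <- .codonAt(trial, cds[ci, ], pos)
            bad <- if (ca$k == 0L) ca$codon != "ATG"
                   else if (ca$k == ca$ncod - 1L)
                       !(ca$codon %in% .STOP_CODONS)
                   else ca$codon %in% .STOP_CODONS
            if (bad) { ok <- FALSE; break }
        }
        if (ok) return(b)
    }
    NA_character_
}

# write base `b` at `pos`, requiring frame-consistency for every covering
# CDS except row `exempt` (whose fixed codon is being restored)
.forceBase <- function(chars, pos, b, features, exempt) {
    cds <- features[features$kind == "CDS", , drop = FALSE]
    covering <- setdiff(which(cds$start <= pos & cds$end >= pos), exempt)
    trial <- chars
    trial[pos] <- b
    for (ci in covering) {
        ca <- .codonAt(trial, cds[ci, ], pos)
        bad <- if (ca$k == 0L) ca$codon != "ATG"
               else if (ca$k == ca$ncod - 1L) !(ca$codon %in% .STOP_CODONS)
               else ca$codon %in% .STOP_CODONS
        if (bad) return(NULL)
    }
    trial
}

# restore a fixed codon (start ATG or terminal stop) of CDS row i whose
# coding-space positions are codonIdx (genome coordinates in coding order);
# tries every allowed codon, returns updated chars or NULL
.restoreFixedCodon <- function(chars, codonIdx, strand, options, features,
                               exempt) {
    for (want in options) {
        letters <- strsplit(want, "")[[1]]
        if (strand == "-") letters <- .compChars(letters)
        trial <- chars
        ok <- TRUE
        for (j in 1:3) {
            if (trial[codonIdx[j]] == letters[j]) next
            t2 <- .forceBase(trial, codonIdx[j], letters[j], features, exempt)
            if (is.null(t2)) { ok <- FALSE; break }
            trial <- t2
        }
        if (ok) return(trial)
    }
    NULL
}

# fix violations (re)introduced by carving overlapping genes: broken start /
# terminal codons are restored and internal stops removed, each edit under
# the frame-consistency rule for all other covering genes; warns about
# anything no substitution can fix
.repairInternalStops <- function(chars, features) {
    cds <- features[features$kind == "CDS", , drop = FALSE]

    for (sweep in 1:10) {
        dirty <- FALSE
        for (i in seq_len(nrow(cds))) {
            r <- cds[i, ]
            idx <- r$start:r$end
            if (r$strand == "-") idx <- rev(idx)
            seqc <- chars[idx]
            if (r$strand == "-") seqc <- .compChars(seqc)
            ncod <- length(seqc) %/% 3L
            startCod <- paste(seqc[1:3], collapse = "")
            stopCod <- paste(seqc[(3 * ncod - 2):(3 * ncod)], collapse = "")
            if (startCod != "ATG") {
                t2 <- .restoreFixedCodon(chars, idx[1:3], r$strand, "ATG",
                                         features, i)
                if (!is.null(t2)) { chars <- t2; dirty <- TRUE }

            }
            if (!(stopCod %in% .STOP_CODONS)) {
                t2 <- .restoreFixedCodon(chars,
                    idx[(3 * ncod - 2):(3 * ncod)], r$strand,
                    sample(.STOP_CODONS), features, i)
                if (!is.null(t2)) { chars <- t2; dirty <- TRUE }

            }
        }
        for (i in seq_len(nrow(cds))) {
            r <- cds[i, ]
            idx <- r$start:r$end
            if (r$strand == "-") idx <- rev(idx)
            seqc <- chars[idx]
            if (r$strand == "-") seqc <- .compChars(seqc)
            ncod <- length(seqc) %/% 3L
            for (k in seq_len(ncod - 2L)) {      # internal codons (0-based k)
                cod <- paste(seqc[(3 * k + 1):(3 * k + 3)], collapse = "")
                if (!(cod %in% .STOP_CODONS)) next
                fixed <- FALSE
                for (off in c(3L, 2L, 1L)) {     # genome position of the base
                    pos <- idx[3 * k + off]
                    b <- .consistentSubstitution(chars, pos, features)
                    if (!is.na(b)) {
                        chars[pos] <- b
                        ca <- .codonAt(chars, r, pos)
                        if (!(ca$codon %in% .STOP_CODONS)) {
                            fixed <- TRUE; dirty <- TRUE; break
                        }
                        # substitution was frame-consistent but left this
                        # codon a stop; keep it and try another position
                        dirty <- TRUE
                    }
                }
                # refresh the local copy after edits
                seqc <- chars[idx]
                if (r$strand == "-") seqc <- .compChars(seqc)
            }
        }
        if (!dirty) break
    }
    # junction fallback: single substitutions cannot untangle some
    # interlocked constraints at gene junctions; re-randomize the free bases
    # around whatever is still broken (re-choosing stop codons) until the
    # local constraint system is satisfied
    viol <- .cdsViolations(chars, features)
    tries <- 0L
    while (nrow(viol) && tries < 5L) {
        for (v in seq_len(nrow(viol))) {
            t2 <- .rerollJunction(chars, features,
                                  c(viol$p1[v], viol$p2[v], viol$p3[v]))
            if (!is.null(t2)) chars <- t2
        }
        viol <- .cdsViolations(chars, features)
        tries <- tries + 1L
    }
    if (nrow(viol))
        warning("unrepairable CDS constraint violations in: ",
                paste(unique(viol$label), collapse = ", "))
    chars
}

# all remaining ORF-constraint violations: start != ATG, terminal not a
# stop, or an internal stop; one row per offending codon with its genome
# positions in coding order
.cdsViolations <- function(chars, features) {
    cds <- features[features$kind == "CDS", , drop = FALSE]
    out <- list()
    for (i in seq_len(nrow(cds))) {
        r <- cds[i, ]
        idx <- r$start:r$end
        if (r$strand == "-") idx <- rev(idx)
        seqc <- chars[idx]
        if (r$strand == "-") seqc <- .compChars(seqc)
        ncod <- length(seqc) %/% 3L
        for (k in 0:(ncod - 1L)) {
            cod <- paste(seqc[(3 * k + 1):(3 * k + 3)], collapse = "")
            bad <- if (k == 0L) cod != "ATG"
                   else if (k == ncod - 1L) !(cod %in% .STOP_CODONS)
                   else cod %in% .STOP_CODONS
            if (bad)
                out[[length(out) + 1L]] <- data.frame(
                    label = r$label, p1 = idx[3 * k + 1L],
                    p2 = idx[3 * k + 2L], p3 = idx[3 * k + 3L],
                    stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(label = character(0), p1 = integer(0),
                          p2 = integer(0), p3 = integer(0)))
    do.call(rbind, out)
}

# every codon of every CDS touching `checkPos` satisfies the ORF rules
.windowValid <- function(chars, features, checkPos) {
    cds <- features[features$kind == "CDS", , drop = FALSE]
    for (i in seq_len(nrow(cds))) {
        r <- cds[i, ]
        hit <- checkPos[checkPos >= r$start & checkPos <= r$end]
        if (!length(hit)) next
        idx <- r$start:r$end
        if (r$strand == "-") idx <- rev(idx)
        seqc <- chars[idx]
        if (r$strand == "-") seqc <- .compChars(seqc)
        ncod <- length(seqc) %/% 3L
        off <- match(hit, idx)
        for (k in unique((off - 1L) %/% 3L)) {
            cod <- paste(seqc[(3 * k + 1):(3 * k + 3)], collapse = "")
            bad <- if (k == 0L) cod != "ATG"
                   else if (k == ncod - 1L) !(cod %in% .STOP_CODONS)
                   else cod %in% .STOP_CODONS
            if (bad) return(FALSE)
        }
    }
    TRUE
}

# re-randomize the free bases in a window around an unrepairable codon,
# re-choosing the stop codons of any terminal codon in reach, until the
# local constraints are satisfiable; start codons are never moved
.rerollJunction <- function(chars, features, codonPos, pad = 6L,
                            attempts = 300L) {
    n <- length(chars)
    win <- max(1L, min(codonPos) - pad):min(n, max(codonPos) + pad)
    cds <- features[features$kind == "CDS", , drop = FALSE]
    startPos <- termIdx <- list()
    for (i in seq_len(nrow(cds))) {
        r <- cds[i, ]
        idx <- r$start:r$end
        if (r$strand == "-") idx <- rev(idx)
        ncod <- length(idx) %/% 3L
        startPos[[i]] <- idx[1:3]
        termIdx[[i]] <- idx[(3 * ncod - 2L):(3 * ncod)]
    }
    keep <- unlist(startPos)                       # ATG positions stay put
    reTerm <- Filter(function(j) any(termIdx[[j]] %in% win),
                     seq_along(termIdx))
    termPosAll <- unlist(termIdx)
    free <- setdiff(win, c(keep, termPosAll))
    checkPos <- unique(c(win, unlist(termIdx[reTerm])))
    strands <- cds$strand
    for (a in seq_len(attempts)) {
        trial <- chars
        if (length(free))
            trial[free] <- sample(c("A", "C", "G", "T"), length(free),
                                  replace = TRUE)
        for (j in reTerm) {
            letters <- strsplit(sample(.STOP_CODONS, 1L), "")[[1]]
            if (strands[j] == "-") letters <- .compChars(letters)
            trial[termIdx[[j]]] <- letters
        }
        if (.windowValid(trial, features, checkPos)) return(trial)
    }
    NULL
}

# plant each recognition once (in a non-coding gap near the requested
# position) and destroy accidental occurrences elsewhere on the circle.
# repeatRegion marks the unit positions duplicated on the physical molecule
# (the terminal repeat / overhang): a site planted there would cut the
# molecule twice, so those positions are treated as unavailable.
.plantSites <- function(chars, features, sites, repeatRegion = integer(0)) {
    n <- length(chars)
    planted <- integer(nrow(sites))
    covered <- rep(FALSE, n)
    covered[repeatRegion] <- TRUE
    for (i in seq_len(nrow(features)))
        covered[features$start[i]:features$end[i]] <- TRUE
    for (i in seq_len(nrow(sites))) {
        m <- nchar(sites$recognition[i])
        want <- .circIdx(sites$position[i], n)
        # nearest run of >= m uncovered positions (no wrap, away from pos 1)
        free <- which(!covered)
        if (!length(free)) stop("no non-coding space to plant sites")
        runs <- split(free, cumsum(c(1L, diff(free) != 1L)))
        runs <- Filter(function(r) length(r) >= m + 2L, runs)
        if (!length(runs))
            stop("no non-coding gap is wide enough for the recognition site")
        runStart <- vapply(runs, function(r) r[1L], 1L)
        best <- runs[[which.min(vapply(runs, function(r)
            min(abs(r[1L] - want), abs(r[length(r)] - want)), 1))]]
        at <- best[2L]                           # 1 nt margin inside the gap
        chars[at:(at + m - 1L)] <- strsplit(sites$recognition[i], "")[[1]]
        covered[at:(at + m - 1L)] <- TRUE
        planted[i] <- at
    }
    # destroy accidental occurrences (circular scan, both strands)
    for (attempt in seq_len(1000L)) {
        s <- paste(chars, collapse = "")
        clean <- TRUE
        for (i in seq_len(nrow(sites))) {
            pat <- sites$recognition[i]
            hits <- .circMatches(pat, s)
            if (!.isPalindromic(pat))
                hits <- sort(unique(c(hits, .circMatches(.revcomp(pat), s))))
            extra <- setdiff(hits, planted[i])
            if (length(extra)) {
                clean <- FALSE
                # destroy the occurrence: prefer the middle base, fall back
                # to any base of the site a consistent substitution exists for
                offs <- order(abs(seq_len(nchar(pat)) - (nchar(pat) + 1) / 2))
                done <- FALSE
                for (off in offs) {
                    pos <- .circIdx(extra[1L] + off - 1L, length(chars))
                    b <- .consistentSubstitution(chars, pos, features)
                    if (!is.na(b)) { chars[pos] <- b; done <- TRUE; break }
                }
                if (!done)
                    stop("cannot destroy an accidental occurrence of ",
                         pat, " at position ", extra[1L])
                break
            }
        }
        if (clean) return(list(chars = chars, positions = planted))
    }
    stop("could not make planted recognition sites unique in 1000 attempts")
}

#' Generate a synthetic phage genome with known ground truth
#'
#' Produces the physical molecule, its circular assembly unit, and a ground
#' truth record, deterministically from the spec and its seed. The background
#' sequence is drawn at the target GC with a planted GC-skew switch; CDS and
#' tRNA features are laid out to the non-coding target (CDS get ATG starts,
#' terminal stops, and internal stops are removed); each planted restriction
#' recognition ends up occurring exactly once on the circle.
#'
#' @param spec a \code{\link{syntheticGenomeSpec}}.
#' @return list with elements \code{molecule}
#'   (\linkS4class{PhysicalMolecule}), \code{assembly} (circular
#'   \linkS4class{GenomeRecord}), and \code{truth} (list: architecture, L,
#'   repeat_seq, site_positions, skew_switch, features).
#' @export
generateGenome <- function(spec) {
    stopifnot(inherits(spec, "SyntheticGenomeSpec"))
    .withSeed(spec$seed, {
        N <- spec$length
        gc <- spec$gcTarget
        amp <- spec$skewAmplitude
        # per-position G/C bias: +amp on (switch, switch + N/2], -amp elsewhere
        if (!is.null(spec$skewSwitch)) {
            posArc <- (.circIdx(seq_len(N) - spec$skewSwitch - 1L, N)) < N %/% 2L
        } else posArc <- rep(TRUE, N)
        ampv <- if (is.null(spec$skewSwitch)) 0 else ifelse(posArc, amp, -amp)
        pG <- gc * (1 + ampv) / 2
        pC <- gc * (1 - ampv) / 2
        u <- runif(N)
        chars <- ifelse(u < pG, "G",
                 ifelse(u < pG + pC, "C",
                 ifelse(u < pG + pC + (1 - gc) / 2, "A", "T")))
        features <- .layoutFeatures(spec)
        if (nrow(features)) {
            chars <- .carveCds(chars, features)
            chars <- .repairInternalStops(chars, features)
        }
        sitePositions <- integer(0)
        if (!is.null(spec$plantedSites) && nrow(spec$plantedSites)) {
            repeatRegion <- switch(spec$architecture,
                blunt = integer(0),
                cos_3 = seq.int(N - spec$L + 1L, N),
                seq_len(spec$L))
            res <- .plantSites(chars, features, spec$plantedSites,
                               repeatRegion)
            chars <- res$chars
            sitePositions <- res$positions
        }
        s <- paste(chars, collapse = "")
        assembly <- GenomeRecord(s, id = sprintf("synthetic_seed%d", spec$seed),
                                 topology = "circular", features = features)
        L <- spec$L
        repSeq <- switch(spec$architecture,
            blunt = "", dtr = substr(s, 1L, L), cos_5 = substr(s, 1L, L),
            cos_3 = substr(s, N - L + 1L, N))
        call <- new("TerminusCall", category = spec$architecture,
                    L = L, repeatSeq = repSeq, a = 1L,
                    b = as.integer(switch(spec$architecture,
                        blunt = N, dtr = L, cos_5 = L, cos_3 = N - L)),
                    notes = "planted")
        molecule <- reconstructPhysical(assembly, call)
        truth <- list(architecture = spec$architecture, L = L,
                      repeat_seq = repSeq,
                      site_positions = sitePositions,
                      site_recognitions = if (length(sitePositions))
                          spec$plantedSites$recognition else character(0),
                      skew_switch = spec$skewSwitch,
                      features = features, a = 1L, b = call@b)
        list(molecule = molecule, assembly = assembly, truth = truth)
    })
}

#' Simulate the two terminal run-off reads for a molecule
#'
#' Convenience wrapper choosing primer positions so that each read spans the
#' full terminal repeat / overhang plus \code{anchor} unique bases.
#'
#' @param molecule a \linkS4class{PhysicalMolecule}.
#' @param anchor unique (non-repeat) bases each read should contain
#'   (default 500).
#' @return list with \code{right} and \code{left} \linkS4class{TerminalRead}s.
#' @export
simulateTerminalReads <- function(molecule, anchor = 500L) {
    d <- .moleculeDuplex(molecule)
    L <- repeatLength(molecule)
    readLen <- anchor + L
    # plus-strand read: ends at the bottom strand's 5' end (right physical end)
    uPos <- d$b2 - readLen + 1L
    primerPlus <- uPos - d$t1 + 1L
    if (primerPlus < 1L)
        stop("molecule too short for the requested anchor")
    right <- simulateRunoff(molecule, primerPlus, "+")
    # minus-strand read: covers the first readLen top-strand bases
    left <- simulateRunoff(molecule, readLen, "-")
    list(right = right, left = left)
}

#' Generate synthetic proteomes with a planted core genome
#'
#' Core families are mutated copies of a common ancestor protein (far above
#' the homology threshold); non-core genes are independent random sequences
#' (far below it).
#'
#' @param nProteomes number of proteomes (>= 2).
#' @param nGenes genes per proteome.
#' @param nCore planted core families (<= nGenes).
#' @param seed integer seed.
#' @param lenRange protein length range (aa).
#' @param mutRate per-site substitution rate applied to each core-family copy.
#' @return list with \code{proteomes} (list of named character vectors; core
#'   genes occupy the first \code{nCore} slots of each) and \code{truth}
#'   (list: core_indices).
#' @export
generateProteomes <- function(nProteomes, nGenes, nCore, seed = 1L,
                              lenRange = c(80L, 300L), mutRate = 0.05) {
    stopifnot(nProteomes >= 2L, nCore <= nGenes)
    aa <- names(.AA_AVG)
    .withSeed(seed, {
        randProt <- function()
            paste(sample(aa, sample(lenRange[1]:lenRange[2], 1L),
                         replace = TRUE), collapse = "")
        mutate <- function(p) {
            ch <- strsplit(p, "")[[1]]
            k <- rbinom(1L, length(ch), mutRate)
            if (k > 0L) {
                at <- sample.int(length(ch), k)
                ch[at] <- vapply(ch[at], function(old)
                    sample(setdiff(aa, old), 1L), character(1))
            }
            paste(ch, collapse = "")
        }
        ancestors <- replicate(nCore, randProt())
        proteomes <- lapply(seq_len(nProteomes), function(p) {
            core <- vapply(ancestors, mutate, character(1), USE.NAMES = FALSE)
            rest <- replicate(nGenes - nCore, randProt())
            setNames(c(core, rest), sprintf("p%d_g%03d", p, seq_len(nGenes)))
        })
        list(proteomes = proteomes,
             truth = list(core_indices = seq_len(nCore)))
    })
}
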