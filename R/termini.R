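#' Construct a PhysicalMolecule
#'
#' @param unionSeq top-strand-sense sequence over the union of both strands
#'   (see \linkS4class{PhysicalMolecule} for the per-architecture layout).
#' @param architecture \code{"blunt"}, \code{"cos_3"}, \code{"cos_5"} or
#'   \code{"dtr"}.
#' @param L overhang / terminal-repeat length (bp).
#' @return a \linkS4class{PhysicalMolecule}.
#' @export
PhysicalMolecule <- function(unionSeq, architecture = "blunt", L = 0L) {
    new("PhysicalMolecule",
        unionSeq = Biostrings::DNAString(.asDnaChar(unionSeq)),
        architecture = architecture, L = as.integer(L))
}

#' @rdname PhysicalMolecule-class
#' @aliases architecture repeatLength topStrand
#' @export
setMethod("architecture", "PhysicalMolecule", function(x) x@architecture)

#' @rdname PhysicalMolecule-class
#' @export
setMethod("repeatLength", "PhysicalMolecule", function(x) x@L)

#' @rdname PhysicalMolecule-class
#' @export
setMethod("topStrand", "PhysicalMolecule", function(x) {
    d <- .moleculeDuplex(x)
    substr(d$u, d$t1, d$t2)
})

#' @rdname PhysicalMolecule-class
#' @export
setMethod("length", "PhysicalMolecule", function(x) {
    d <- .moleculeDuplex(x)
    max(d$t2 - d$t1, d$b2 - d$b1) + 1L
})

setMethod("show", "PhysicalMolecule", function(object) {
    cat(sprintf("PhysicalMolecule: %s, strand length %d nt, L = %d\n",
                object@architecture, length(object), object@L))
})

#' @rdname s1Trim
#' @export
setMethod("s1Trim", "PhysicalMolecule", function(x) {
    if (x@architecture %in% c("blunt", "dtr")) return(x)
    d <- .moleculeDuplex(x)
    s <- max(d$t1, d$b1); e <- min(d$t2, d$b2)
    PhysicalMolecule(substr(d$u, s, e), "blunt", 0L)
})

#' Simulate a terminal run-off sequencing read
#'
#' A primer annealed to one strand is extended by polymerase until the
#' template strand ends; the read therefore terminates exactly at a physical
#' end of the molecule. A plus-strand primer (template: bottom strand) yields
#' a top-strand-sense read running off the right end; a minus-strand primer
#' (template: top strand) yields a read running off the left end, reported as
#' sequenced (complementary to the top strand).
#'
#' @param molecule a \linkS4class{PhysicalMolecule}.
#' @param primerPos primer coordinate on the top strand: for \code{"+"} the
#'   read starts at this position; for \code{"-"} the read covers top
#'   positions 1..primerPos (then reverse-complemented).
#' @param strand \code{"+"} or \code{"-"}.
#' @return a \linkS4class{TerminalRead}.
#' @examples
#' mol <- PhysicalMolecule(paste(rep("ACGTTGCAAC", 10), collapse = ""))
#' simulateRunoff(mol, 91, "+")  # 10 nt read: bases 91..100
#' @export
simulateRunoff <- function(molecule, primerPos, strand = c("+", "-")) {
    strand <- match.arg(strand)
    stopifnot(is(molecule, "PhysicalMolecule"))
    d <- .moleculeDuplex(molecule)
    nTop <- d$t2 - d$t1 + 1L
    primerPos <- as.integer(primerPos)
    if (primerPos < 1L || primerPos > nTop)
        stop("primer does not anneal within the molecule (top strand is ",
             nTop, " nt)")
    uPos <- d$t1 + primerPos - 1L
    if (strand == "+") {
        if (uPos > d$b2) stop("plus-strand primer has no template")
        seq <- substr(d$u, uPos, d$b2)
        new("TerminalRead", sequence = Biostrings::DNAString(seq),
            side = "right_end", primerPos = primerPos, errorFree = TRUE)
    } else {
        seq <- .revcomp(substr(d$u, d$t1, uPos))
        new("TerminalRead", sequence = Biostrings::DNAString(seq),
            side = "left_end", primerPos = primerPos, errorFree = TRUE)
    }
}

setMethod("show", "TerminalRead", function(object) {
    cat(sprintf("TerminalRead (%s): %d nt from primer at %d\n",
                object@side, length(object@sequence), object@primerPos))
})

# unique circular mapping of `read` (top-sense) on circle `s`; error if
# ambiguous. With maxMismatchRate > 0, maps by a 20 nt exact seed at the read
# start, then accepts the locus if total mismatches <= rate * length.
.mapReadCircular <- function(read, s, what, maxMismatchRate = 0) {
    n <- nchar(s)
    if (nchar(read) > n)
        stop(what, " is longer than the assembly unit")
    if (maxMismatchRate <= 0) {
        starts <- .circMatches(read, s)
    } else {
        seedLen <- min(20L, nchar(read))
        seeds <- .circMatches(substr(read, 1L, seedLen), s)
        doubled <- paste0(s, s)
        rchars <- strsplit(read, "")[[1]]
        starts <- seeds[vapply(seeds, function(p) {
            loc <- strsplit(substr(doubled, p, p + nchar(read) - 1L), "")[[1]]
            sum(loc != rchars) <= maxMismatchRate * nchar(read)
        }, logical(1))]
    }
    if (length(starts) == 0L)
        stop(what, " does not map to the assembly (exact match required)")
    if (length(starts) > 1L)
        stop(what, " maps to multiple assembly loci: ",
             paste(starts, collapse = ", "))
    starts
}

# longest k in [minK, maxK] with suffix(right, k) == prefix(left, k)
.longestSharedTerminal <- function(right, left, minK) {
    maxK <- min(nchar(right), nchar(left))
    if (maxK < minK) return(0L)
    firstLeft <- substr(left, 1L, 1L)
    rchars <- strsplit(right, "")[[1]]
    nr <- length(rchars)
    candidates <- which(rchars == firstLeft)          # suffix start positions
    ks <- nr - candidates + 1L
    ks <- sort(ks[ks >= minK & ks <= maxK], decreasing = TRUE)
    for (k in ks) {
        if (substr(right, nr - k + 1L, nr) == substr(left, 1L, k))
            return(k)
    }
    0L
}

#' Classify genome termini from a circular assembly and two run-off reads
#'
#' Implements the three-case decision rule for phage genome ends. The
#' right-end read (plus strand) and left-end read (minus strand, as
#' sequenced) are mapped to the circular assembly; the terminal base of the
#' right read marks the right physical end \code{b}, the start of the
#' reverse-complemented left read marks the left physical end \code{a}.
#' The longest exact shared terminal region between the two reads (suffix of
#' the right read equal to a prefix of the reverse-complemented left read)
#' decides the call:
#' \itemize{
#'   \item no shared region and \code{a == b + 1} on the circle: blunt ends;
#'   \item no shared region but a gap of \code{g > 0} assembly bases between
#'     \code{b} and \code{a}: 3'-protruding cohesive ends of length \code{g}
#'     (the overhang is the assembly arc in the gap);
#'   \item a shared region of length \code{L} with
#'     \code{minOverlap <= L < threshold}: 5'-protruding cohesive ends;
#'   \item \code{L >= threshold}: terminal redundancy (dtr).
#' }
#' Shared regions shorter than \code{minOverlap} are treated as chance
#' micro-overlaps and resolved through the gap rule, with a warning.
#'
#' @param assembly circular \linkS4class{GenomeRecord}.
#' @param readRight right-end \linkS4class{TerminalRead} (or character).
#' @param readLeft left-end \linkS4class{TerminalRead} (or character, as
#'   sequenced).
#' @param threshold repeat length (bp) at and above which a shared region is
#'   called terminal redundancy rather than a cohesive 5' end (default 100).
#' @param minOverlap minimum exact shared length accepted as a real overlap
#'   (default 4).
#' @param maxMismatchRate mismatch tolerance for read mapping (default 0:
#'   exact); when positive, reads are anchored by a 20 nt exact seed and
#'   accepted at up to this mismatch fraction.
#' @return a \linkS4class{TerminusCall}.
#' @export
classifyTermini <- function(assembly, readRight, readLeft, threshold = 100L,
                            minOverlap = 4L, maxMismatchRate = 0) {
    stopifnot(is(assembly, "GenomeRecord"))
    if (topology(assembly) != "circular")
        stop("classifyTermini expects a circular assembly")
    right <- if (is(readRight, "TerminalRead"))
        as.character(readRight@sequence) else .asDnaChar(readRight)
    leftSeq <- if (is(readLeft, "TerminalRead"))
        as.character(readLeft@sequence) else .asDnaChar(readLeft)
    left <- .revcomp(leftSeq)                    # top-strand sense
    if (nchar(right) < 2L * minOverlap || nchar(left) < 2L * minOverlap)
        stop("reads too short to anchor (< 2 * minOverlap nt)")
    s <- as.character(genomeSeq(assembly))
    n <- nchar(s)
    rStart <- .mapReadCircular(right, s, "right-end read", maxMismatchRate)
    a <- .mapReadCircular(left, s, "left-end read", maxMismatchRate)
    b <- .circIdx(rStart + nchar(right) - 1L, n)
    # arc length from a to b on the circle: the putative shared region
    arc <- (b - a) %% n + 1L
    notes <- character(0)
    shared <- FALSE
    if (arc <= min(nchar(right), nchar(left))) {
        nr <- nchar(right)
        shared <- substr(right, nr - arc + 1L, nr) == substr(left, 1L, arc)
        if (!shared)
            notes <- c(notes, sprintf(
                "coordinate overlap of %d bp is not an exact sequence match between the reads; resolved through the gap rule",
                arc))
        else if (arc < minOverlap)
            notes <- c(notes, sprintf(
                "shared region of %d nt is below minOverlap = %d but coordinate-supported; accepted",
                arc, minOverlap))
    }
    # reads may also share a terminal region by chance at a length that is
    # not coordinate-consistent; such matches are rejected (with a note)
    if (!shared) {
        k <- .longestSharedTerminal(right, left, minOverlap)
        if (k > 0L && k != arc)
            notes <- c(notes, sprintf(
                "ignoring %d nt chance shared region inconsistent with read coordinates", k))
    }
    if (shared) {
        L <- as.integer(arc)
        category <- if (L >= threshold) "dtr" else "cos_5"
        repSeq <- substr(left, 1L, L)
    } else {
        g <- (a - b - 1L) %% n
        if (g == 0L) {
            category <- "blunt"; L <- 0L; repSeq <- ""
        } else {
            category <- "cos_3"; L <- as.integer(g)
            repSeq <- .circArc(s, b + 1L, a - 1L)
        }
    }
    new("TerminusCall", category = category, L = as.integer(L),
        repeatSeq = repSeq, a = as.integer(a), b = as.integer(b),
        notes = if (length(notes)) paste(notes, collapse = "; ") else "")
}

setMethod("show", "TerminusCall", function(object) {
    cat(sprintf("TerminusCall: %s, L = %d, ends a = %d, b = %d\n",
                object@category, object@L, object@a, object@b))
    if (nzchar(object@notes)) cat("  notes:", object@notes, "\n")
})

#' Convert a TerminusCall to a list (JSON-ready)
#' @param call a \linkS4class{TerminusCall}.
#' @return a named list.
#' @export
terminusCallAsList <- function(call) {
    list(category = call@category, L = call@L, repeat_or_overhang_seq =
         call@repeatSeq, a = call@a, b = call@b, notes = call@notes)
}

#' Reconstruct the physical genome molecule from a terminus call
#'
#' Rotates the circular assembly unit so the left physical end is first, then
#' applies the called architecture: a blunt call yields the N bp duplex; a
#' dtr call appends a second copy of the terminal repeat (physical length
#' N + L, first L bases equal to the last L); a cohesive call yields the N bp
#' duplex with L nt complementary single-stranded extensions.
#'
#' @param assembly circular \linkS4class{GenomeRecord} of unit length N.
#' @param call a \linkS4class{TerminusCall} produced from this assembly.
#' @return a \linkS4class{PhysicalMolecule}.
#' @export
reconstructPhysical <- function(assembly, call) {
    stopifnot(is(assembly, "GenomeRecord"), is(call, "TerminusCall"))
    s <- as.character(genomeSeq(assembly))
    n <- nchar(s)
    rot <- .rotateSeq(s, call@a)
    L <- call@L
    if (call@category != "blunt") {
        expect <- switch(call@category,
            dtr = substr(rot, 1L, L),
            cos_5 = substr(rot, 1L, L),
            cos_3 = substr(rot, n - L + 1L, n))
        if (!identical(call@repeatSeq, expect))
            stop("inconsistent call: repeat/overhang sequence not found at ",
                 "the expected assembly coordinates")
    }
    switch(call@category,
        blunt = PhysicalMolecule(rot, "blunt", 0L),
        dtr = PhysicalMolecule(paste0(rot, substr(rot, 1L, L)), "dtr", L),
        cos_5 = PhysicalMolecule(paste0(rot, substr(rot, 1L, L)), "cos_5", L),
        cos_3 = PhysicalMolecule(paste0(substr(rot, n - L + 1L, n), rot),
                                 "cos_3", L))
}
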