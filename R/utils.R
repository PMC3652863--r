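# internal sequence helpers; all coordinates 1-based inclusive

.asDnaChar <- function(x) {
    if (is(x, "DNAString") || is(x, "DNAStringSet")) return(as.character(x))
    toupper(as.character(x))
}

.revcomp <- function(x) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.comp <- function(x) chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN", x)

# map a (possibly out-of-range) coordinate onto a circle of size n
.circIdx <- function(i, n) ((i - 1L) %% n) + 1L

# rotate so that position `start` becomes position 1
.rotateSeq <- function(s, start) {
    n <- nchar(s)
    start <- .circIdx(start, n)
    if (start == 1L) return(s)
    paste0(substr(s, start, n), substr(s, 1L, start - 1L))
}

# extract an arc from a circular sequence, wrapping if from > to
.circArc <- function(s, from, to) {
    n <- nchar(s)
    from <- .circIdx(from, n)
    to <- .circIdx(to, n)
    if (from <= to) substr(s, from, to)
    else paste0(substr(s, from, n), substr(s, 1L, to))
}

# all exact match start positions of `pattern` in circular sequence `s`
# (starts reported in 1..n)
.circMatches <- function(pattern, s) {
    n <- nchar(s)
    m <- nchar(pattern)
    if (m > n) return(integer(0))
    doubled <- paste0(s, substr(s, 1L, m - 1L))
    hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(doubled))
    starts <- BiocGenerics::start(hits)
    starts[starts <= n]
}

.linMatches <- function(pattern, s) {
    hits <- Biostrings::matchPattern(pattern, Biostrings::DNAString(s))
    BiocGenerics::start(hits)
}

# deterministic RNG scope: evaluate `expr` under a local seed without
# touching the caller's RNG state
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

.randomDna <- function(n, pG, pC, pA = NULL, pT = NULL) {
    gc <- pG + pC
    if (is.null(pA)) pA <- (1 - gc) / 2
    if (is.null(pT)) pT <- 1 - gc - pA
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                 prob = c(pA, pC, pG, pT)), collapse = "")
}
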