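# Independent brute-force oracles used to validate the package's optimized
# implementations. These are written from the documented definitions, not
# from the package's code paths.

## ---- exact maximal repeat oracle (O(n^2) diagonal scan) ---------------------

# match predicate tables
.OR_COMP <- c(A = "T", C = "G", G = "C", T = "A")

oracle_repeats <- function(s, kind, minLen) {
    ch <- strsplit(toupper(s), "")[[1]]
    n <- length(ch)
    acgt <- ch %in% c("A", "C", "G", "T")
    out <- list()
    if (kind == "direct") {
        if (n >= 2L) for (d in seq_len(n - 1L)) {
            idx <- seq_len(n - d)
            m <- acgt[idx] & acgt[idx + d] & ch[idx] == ch[idx + d]
            r <- rle(m)
            ends <- cumsum(r$lengths)
            starts <- ends - r$lengths + 1L
            for (k in which(r$values & r$lengths >= minLen))
                out[[length(out) + 1L]] <-
                    c(starts[k], starts[k] + d, r$lengths[k])
        }
    } else {
        compl <- kind == "inverted"
        # anti-diagonal cc = q + p (1-based); q matches p = cc - q
        for (cc in seq_len(2L * n - 1L) + 1L) {
            qs <- seq.int(max(1L, cc - n), min(n, cc - 1L))
            ps <- cc - qs
            m <- acgt[qs] & acgt[ps] &
                (if (compl) ch[qs] == .OR_COMP[ch[ps]] else ch[qs] == ch[ps])
            r <- rle(m)
            ends <- cumsum(r$lengths)
            starts <- ends - r$lengths + 1L
            for (k in which(r$values)) {
                x <- qs[starts[k]]; y <- qs[ends[k]]
                R <- y - x + 1L
                if (x == cc - y) {           # symmetric centre-crossing run
                    l <- R %/% 2L
                    p1 <- x; p2 <- y - l + 1L
                } else if (x + y > cc) {     # run right of centre
                    p1 <- cc - y; p2 <- x; l <- R
                } else next                  # left twin of a right-run
                if (l >= minLen && p1 + l - 1L < p2)
                    out[[length(out) + 1L]] <- c(p1, p2, l)
            }
        }
    }
    if (!length(out))
        return(data.frame(pos1 = integer(0), pos2 = integer(0),
                          length = integer(0)))
    m <- do.call(rbind, out)
    df <- unique(data.frame(pos1 = m[, 1], pos2 = m[, 2], length = m[, 3]))
    df[order(-df$length, df$pos1, df$pos2), , drop = FALSE]
}

# canonical string form of a hit set, for set equality tests
hit_key <- function(df) sort(sprintf("%d:%d:%d", df$pos1, df$pos2, df$length))

## ---- local alignment score oracle (Gotoh, affine gaps) ----------------------

# Smith-Waterman with affine gaps; a gap of length L costs open + L * ext
# (the Biostrings convention). Returns the best local score, floored at 0.
oracle_sw <- function(a, b, mat, open = 11, ext = 1) {
    A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
    na <- length(A); nb <- length(B)
    if (na == 0L || nb == 0L) return(0)
    NEG <- -1e9
    M <- matrix(0, na + 1L, nb + 1L)
    E <- matrix(NEG, na + 1L, nb + 1L)   # gap in A (move along B)
    F <- matrix(NEG, na + 1L, nb + 1L)   # gap in B (move along A)
    best <- 0
    for (i in 2:(na + 1L)) {
        for (j in 2:(nb + 1L)) {
            E[i, j] <- max(M[i, j - 1L] - (open + ext), E[i, j - 1L] - ext)
            F[i, j] <- max(M[i - 1L, j] - (open + ext), F[i - 1L, j] - ext)
            sc <- M[i - 1L, j - 1L] + mat[A[i - 1L], B[j - 1L]]
            M[i, j] <- max(0, sc, E[i, j], F[i, j])
            if (M[i, j] > best) best <- M[i, j]
        }
    }
    best
}

## ---- misc ---------------------------------------------------------------------

random_dna <- function(n, alphabet = c("A", "C", "G", "T"))
    paste(sample(alphabet, n, replace = TRUE), collapse = "")

random_protein <- function(n)
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
                 replace = TRUE), collapse = "")

circ_dist <- function(a, b, n) min(abs(a - b), n - abs(a - b))

# strand-resolved revcomp without Biostrings (independent of package code)
oracle_revcomp <- function(s) {
    ch <- rev(strsplit(toupper(s), "")[[1]])
    paste(c(A = "T", C = "G", G = "C", T = "A")[ch], collapse = "")
}
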