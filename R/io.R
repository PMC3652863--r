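#' Read genome records from FASTA or GenBank flat files
#'
#' FASTA parsing is delegated to \link[Biostrings]{readDNAStringSet}. GenBank
#' flat files are parsed by a focused reader supporting the LOCUS line
#' (length and topology), gene/CDS/tRNA features with \code{start..end},
#' \code{complement(start..end)} and two-segment \code{join(...)} (origin
#' wrap) locations, and single-line \code{/locus_tag}, \code{/gene} and
#' \code{/product} qualifiers.
#'
#' @param path file path.
#' @param format \code{"fasta"} or \code{"genbank"}.
#' @return a list of \linkS4class{GenomeRecord} objects.
#' @seealso \code{\link{writeGenBank}} for the complementary writer.
#' @export
readSequences <- function(path, format = c("fasta", "genbank")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "fasta") {
        set <- Biostrings::readDNAStringSet(path)
        ids <- sub("\\s.*$", "", names(set))
        lapply(seq_along(set), function(i)
            GenomeRecord(toupper(as.character(set[[i]])), id = ids[i]))
    } else {
        .readGenBank(path)
    }
}

.readGenBank <- function(path) {
    lines <- readLines(path, warn = FALSE)
    recs <- list()
    i <- 1L
    n <- length(lines)
    while (i <= n) {
        while (i <= n && !grepl("^LOCUS", lines[i])) {
            if (nzchar(trimws(lines[i])) && !grepl("^//", lines[i]))
                stop("GenBank parse error at line ", i,
                     ": expected LOCUS, got '", lines[i], "'")
            i <- i + 1L
        }
        if (i > n) break
        parsed <- .parseGenBankRecord(lines, i)
        recs[[length(recs) + 1L]] <- parsed$record
        i <- parsed$nextLine
    }
    if (!length(recs)) stop("GenBank parse error: no LOCUS record in ", path)
    recs
}

.parseGenBankRecord <- function(lines, i) {
    locus <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(locus) < 3L)
        stop("GenBank parse error at line ", i, ": malformed LOCUS line")
    id <- locus[2]
    declaredLen <- suppressWarnings(as.integer(locus[3]))
    topology <- if (any(tolower(locus) == "circular")) "circular" else "linear"
    n <- length(lines)
    feats <- .emptyFeatures()
    seqChunks <- character(0)
    i <- i + 1L
    while (i <= n && !grepl("^//", lines[i])) {
        if (grepl("^ACCESSION", lines[i])) {
            acc <- strsplit(trimws(lines[i]), "\\s+")[[1]]
            if (length(acc) >= 2L) id <- acc[2]
            i <- i + 1L
        } else if (grepl("^FEATURES", lines[i])) {
            ft <- .parseGenBankFeatures(lines, i + 1L)
            feats <- ft$features
            i <- ft$nextLine
        } else if (grepl("^ORIGIN", lines[i])) {
            i <- i + 1L
            while (i <= n && !grepl("^//", lines[i])) {
                seqChunks <- c(seqChunks, gsub("[ 0-9/]", "", lines[i]))
                i <- i + 1L
            }
        } else {
            i <- i + 1L
        }
    }
    seq <- toupper(paste(seqChunks, collapse = ""))
    if (!nchar(seq))
        stop("GenBank parse error in record '", id, "': missing ORIGIN sequence")
    if (!is.na(declaredLen) && nchar(seq) != declaredLen)
        warning("record '", id, "': LOCUS declares ", declaredLen,
                " bp but ORIGIN has ", nchar(seq))
    list(record = GenomeRecord(seq, id = id, topology = topology,
                               features = feats),
         nextLine = i + 1L)
}

.parseGenBankFeatures <- function(lines, i) {
    n <- length(lines)
    rows <- list()
    cur <- NULL
    flush <- function() {
        if (!is.null(cur)) rows[[length(rows) + 1L]] <<- cur
        cur <<- NULL
    }
    while (i <= n && grepl("^ {4,}\\S|^ *$", lines[i]) &&
           !grepl("^(ORIGIN|CONTIG|BASE COUNT)", lines[i])) {
        line <- lines[i]
        if (grepl("^ {5}\\S", line)) {           # new feature key
            flush()
            key <- trimws(substr(line, 1, 20))
            loc <- trimws(substr(line, 21, nchar(line)))
            kind <- if (key %in% .FEATURE_KINDS) key else "other"
            if (key == "source") { i <- i + 1L; next }
            parsed <- .parseGenBankLocation(loc, i)
            cur <- data.frame(kind = kind, start = parsed$start,
                              end = parsed$end, strand = parsed$strand,
                              label = "", product = "",
                              wraps = parsed$wraps, stringsAsFactors = FALSE)
        } else if (!is.null(cur) && grepl("^ {21}/", line)) {  # qualifier
            q <- sub("^ {21}/", "", line)
            keyval <- regmatches(q, regexec('^([A-Za-z_]+)="?([^"]*)"?$', q))[[1]]
            if (length(keyval) == 3L) {
                if (keyval[2] %in% c("locus_tag", "gene") && cur$label == "")
                    cur$label <- keyval[3]
                if (keyval[2] == "product") cur$product <- keyval[3]
            }
        }
        i <- i + 1L
    }
    flush()
    features <- if (length(rows)) do.call(rbind, rows) else .emptyFeatures()
    list(features = .normalizeFeatures(features), nextLine = i)
}

.parseGenBankLocation <- function(loc, lineNo) {
    strand <- "+"
    wraps <- FALSE
    if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
    }
    if (grepl("^join\\(", loc)) {
        inner <- sub("^join\\((.*)\\)$", "\\1", loc)
        parts <- strsplit(inner, ",")[[1]]
        if (length(parts) != 2L)
            stop("GenBank parse error at line ", lineNo,
                 ": only two-segment join() locations are supported")
        seg <- lapply(parts, .parseSimpleSpan, lineNo = lineNo)
        return(list(start = seg[[1]]$start, end = seg[[2]]$end,
                    strand = strand, wraps = TRUE))
    }
    span <- .parseSimpleSpan(loc, lineNo)
    list(start = span$start, end = span$end, strand = strand, wraps = wraps)
}

.parseSimpleSpan <- function(loc, lineNo) {
    loc <- gsub("[<>]", "", trimws(loc))
    if (grepl("^[0-9]+\\.\\.[0-9]+$", loc)) {
        parts <- as.integer(strsplit(loc, "\\.\\.")[[1]])
        list(start = parts[1], end = parts[2])
    } else if (grepl("^[0-9]+$", loc)) {
        list(start = as.integer(loc), end = as.integer(loc))
    } else {
        stop("GenBank parse error at line ", lineNo,
             ": unsupported location '", loc, "'")
    }
}

#' Write a GenomeRecord as a GenBank flat file
#'
#' Emits LOCUS, ACCESSION, FEATURES (gene/CDS/tRNA with locus_tag and
#' product) and ORIGIN blocks; round-trips exactly through
#' \code{\link{readSequences}}.
#'
#' @param record a \linkS4class{GenomeRecord}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeGenBank <- function(record, path) {
    stopifnot(is(record, "GenomeRecord"))
    s <- as.character(genomeSeq(record))
    n <- nchar(s)
    topo <- if (topology(record) == "circular") "circular" else "linear"
    out <- c(sprintf("LOCUS       %s %d bp    DNA     %s PHG 01-JAN-2026",
                     record@id, n, topo),
             "DEFINITION  synthetic record.",
             sprintf("ACCESSION   %s", record@id),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", n))
    f <- featureTable(record)
    if (nrow(f)) {
        for (k in seq_len(nrow(f))) {
            loc <- if (f$wraps[k])
                sprintf("join(%d..%d,1..%d)", f$start[k], n, f$end[k])
            else sprintf("%d..%d", f$start[k], f$end[k])
            if (f$strand[k] == "-") loc <- sprintf("complement(%s)", loc)
            key <- f$kind[k]
            out <- c(out, sprintf("     %-16s%s", key, loc))
            if (nzchar(f$label[k]))
                out <- c(out, sprintf('                     /locus_tag="%s"',
                                      f$label[k]))
            if (nzchar(f$product[k]))
                out <- c(out, sprintf('                     /product="%s"',
                                      f$product[k]))
        }
    }
    out <- c(out, "ORIGIN")
    starts <- seq(1L, n, by = 60L)
    for (st in starts) {
        block <- substr(s, st, min(st + 59L, n))
        tens <- substring(block, seq(1, nchar(block), 10),
                          pmin(seq(10, nchar(block) + 9, 10), nchar(block)))
        out <- c(out, sprintf("%9d %s", st, tolower(paste(tens, collapse = " "))))
    }
    out <- c(out, "//")
    writeLines(out, path)
    invisible(path)
}

#' Write a GenomeRecord (or named character sequences) as FASTA
#' @param x a \linkS4class{GenomeRecord}, or a named character vector.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFasta <- function(x, path) {
    if (is(x, "GenomeRecord")) {
        set <- Biostrings::DNAStringSet(setNames(as.character(genomeSeq(x)),
                                                 x@id))
    } else {
        set <- Biostrings::DNAStringSet(x)
    }
    Biostrings::writeXStringSet(set, path)
    invisible(path)
}
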