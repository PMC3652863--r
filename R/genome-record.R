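#' Construct a GenomeRecord
#'
#' @param sequence DNA sequence (character or \link[Biostrings]{DNAString});
#'   uppercased on ingest.
#' @param id identifier string.
#' @param topology \code{"linear"} (default) or \code{"circular"}.
#' @param features optional feature data.frame; missing columns are filled
#'   with defaults (\code{strand = "+"}, empty label/product,
#'   \code{wraps = FALSE}).
#' @return a \linkS4class{GenomeRecord}.
#' @examples
#' gr <- GenomeRecord("ACGTACGT", id = "toy")
#' gcContent(gr)
#' @export
GenomeRecord <- function(sequence, id = "genome", topology = "linear",
                         features = NULL) {
    if (is.null(features)) features <- .emptyFeatures()
    features <- .normalizeFeatures(features)
    new("GenomeRecord", id = id,
        sequence = Biostrings::DNAString(.asDnaChar(sequence)),
        topology = topology, features = features)
}

.normalizeFeatures <- function(f) {
    if (nrow(f) == 0) return(.emptyFeatures())
    if (is.null(f$strand)) f$strand <- "+"
    if (is.null(f$label)) f$label <- ""
    if (is.null(f$product)) f$product <- ""
    if (is.null(f$wraps)) f$wraps <- f$start > f$end
    f$start <- as.integer(f$start)
    f$end <- as.integer(f$end)
    f[, c("kind", "start", "end", "strand", "label", "product", "wraps")]
}

#' @rdname GenomeRecord-class
#' @aliases genomeSeq topology featureTable
#' @export
setMethod("genomeSeq", "GenomeRecord", function(x) x@sequence)

#' @rdname GenomeRecord-class
#' @export
setMethod("topology", "GenomeRecord", function(x) x@topology)

#' @rdname GenomeRecord-class
#' @export
setMethod("featureTable", "GenomeRecord", function(x) x@features)

#' @rdname GenomeRecord-class
#' @export
setMethod("length", "GenomeRecord", function(x) length(x@sequence))

setMethod("show", "GenomeRecord", function(object) {
    f <- object@features
    cat(sprintf("GenomeRecord '%s': %d bp, %s; %d features (%d CDS, %d tRNA)\n",
                object@id, length(object@sequence), object@topology,
                nrow(f), sum(f$kind == "CDS"), sum(f$kind == "tRNA")))
})

#' Feature span lengths (bp), respecting origin wrap
#' @keywords internal
.featureSpan <- function(f, n) {
    ifelse(f$wraps, n - f$start + 1L + f$end, f$end - f$start + 1L)
}
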