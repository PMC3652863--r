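#' @rdname GenomeRecord-class
#' @param object,x an object.
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname GenomeRecord-class
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname GenomeRecord-class
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))

#' @rdname PhysicalMolecule-class
#' @export
setGeneric("architecture", function(x) standardGeneric("architecture"))

#' @rdname PhysicalMolecule-class
#' @export
setGeneric("repeatLength", function(x) standardGeneric("repeatLength"))

#' @rdname PhysicalMolecule-class
#' @export
setGeneric("topStrand", function(x) standardGeneric("topStrand"))

#' Trim single-stranded overhangs (in silico S1 nuclease)
#'
#' S1 nuclease degrades single-stranded DNA. Applied in silico, it removes
#' single-stranded terminal extensions while leaving duplex regions (including
#' a double-stranded terminal repeat) untouched. The operation is idempotent
#' and preserves total length exactly when the architecture is blunt or dtr --
#' the paper-style check that distinguishes terminal redundancy from cohesive
#' ends.
#'
#' @param x a \linkS4class{PhysicalMolecule} or \linkS4class{DNAFragment}.
#' @return an object of the same class with overhangs removed.
#' @export
setGeneric("s1Trim", function(x) standardGeneric("s1Trim"))

#' @rdname DNAFragment-class
#' @export
setGeneric("fragmentLength", function(x) standardGeneric("fragmentLength"))

#' @rdname DNAFragment-class
#' @export
setGeneric("leftOverhang", function(x) standardGeneric("leftOverhang"))

#' @rdname DNAFragment-class
#' @export
setGeneric("rightOverhang", function(x) standardGeneric("rightOverhang"))
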