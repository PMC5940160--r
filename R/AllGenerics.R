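#' @rdname GenotypeData
#' @param x an object.
#' @export
setGeneric("genoCodes", function(x) standardGeneric("genoCodes"))

#' @rdname GenotypeData
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname GenotypeData
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeData
#' @export
setGeneric("isFullyHomozygous", function(x) standardGeneric("isFullyHomozygous"))

#' @rdname GenotypeData
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname GenotypeData
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))

#' @rdname GenomicKernel
#' @param x an object.
#' @export
setGeneric("kernelValues", function(x) standardGeneric("kernelValues"))

#' @rdname GenomicKernel
#' @export
setGeneric("kernelKind", function(x) standardGeneric("kernelKind"))

#' @rdname GenomicKernel
#' @export
setGeneric("kernelMeta", function(x) standardGeneric("kernelMeta"))

#' @rdname BlockPartition
#' @param x an object.
#' @export
setGeneric("blockTable", function(x) standardGeneric("blockTable"))

#' @rdname BlockPartition
#' @export
setGeneric("nBlocks", function(x) standardGeneric("nBlocks"))
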