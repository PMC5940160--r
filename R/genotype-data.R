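#' Construct a GenotypeData object
#'
#' @param codes n x p matrix of marker codes in \{0, 1, 2\}; the (i, j) entry
#'   is the number of copies of the counted allele of marker j carried by
#'   sample i.
#' @param map data.frame with columns `marker_id`, `chrom`, `pos` (1-based
#'   physical position), one row per marker column.  Markers are re-ordered
#'   by (chrom, pos) if needed, together with the code columns.
#' @param sampleIds character vector of sample identifiers; defaults to the
#'   rownames of `codes` or `ind1..indn`.
#'
#' @return a [GenotypeData-class] object.  The `fullyHomozygous` flag is set
#'   by scanning the codes for any heterozygous (1) entry.
#' @examples
#' m <- matrix(c(2, 2, 0, 1), 2, 2, byrow = TRUE)
#' g <- GenotypeData(m, data.frame(marker_id = c("m1", "m2"),
#'                                 chrom = "1", pos = c(100, 200)))
#' isFullyHomozygous(g)
#' @export
GenotypeData <- function(codes, map, sampleIds = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "double"
  map <- as.data.frame(map)
  if (!all(c("marker_id", "chrom", "pos") %in% names(map)))
    stop("map must have columns marker_id, chrom, pos")
  map$marker_id <- as.character(map$marker_id)
  map$chrom <- as.character(map$chrom)
  o <- order(map$chrom, map$pos)
  if (!identical(o, seq_len(nrow(map)))) {
    map <- map[o, , drop = FALSE]
    codes <- codes[, o, drop = FALSE]
  }
  rownames(map) <- NULL
  if (is.null(sampleIds))
    sampleIds <- rownames(codes)
  if (is.null(sampleIds))
    sampleIds <- paste0("ind", seq_len(nrow(codes)))
  dimnames(codes) <- list(as.character(sampleIds), map$marker_id)
  new("GenotypeData", codes = codes, map = map,
      fullyHomozygous = !any(codes == 1))
}

#' @rdname GenotypeData
#' @export
setMethod("genoCodes", "GenotypeData", function(x) x@codes)

#' @rdname GenotypeData
#' @export
setMethod("markerMap", "GenotypeData", function(x) x@map)

#' @rdname GenotypeData
#' @export
setMethod("sampleIds", "GenotypeData", function(x) rownames(x@codes))

#' @rdname GenotypeData
#' @export
setMethod("isFullyHomozygous", "GenotypeData", function(x) x@fullyHomozygous)

#' @rdname GenotypeData
#' @export
setMethod("nSamples", "GenotypeData", function(x) nrow(x@codes))

#' @rdname GenotypeData
#' @export
setMethod("nMarkers", "GenotypeData", function(x) ncol(x@codes))

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object@codes), "samples x",
      ncol(object@codes), "markers\n")
  cat("  chromosomes:", length(unique(object@map$chrom)), "\n")
  cat("  fully homozygous:", object@fullyHomozygous, "\n")
})

#' Subset a genotype panel by samples and/or markers
#'
#' @param x a [GenotypeData-class] object.
#' @param i sample index (integer, logical or character ids).
#' @param j marker index.
#' @param ... ignored.
#' @param drop ignored; the result is always a GenotypeData.
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  cd <- x@codes
  mp <- x@map
  if (!missing(j)) {
    cd <- cd[, j, drop = FALSE]
    mp <- mp[j, , drop = FALSE]
  }
  if (!missing(i)) cd <- cd[i, , drop = FALSE]
  GenotypeData(cd, mp)
})

#' @rdname PhasedGenotypes
#' @param maternal,paternal n x p matrices in \{0, 1\}.
#' @param map marker map.
#' @export
PhasedGenotypes <- function(maternal, paternal, map) {
  maternal <- as.matrix(maternal); storage.mode(maternal) <- "double"
  paternal <- as.matrix(paternal); storage.mode(paternal) <- "double"
  dimnames(paternal) <- dimnames(maternal)
  new("PhasedGenotypes", maternal = maternal, paternal = paternal,
      map = as.data.frame(map))
}

#' @rdname PhasedGenotypes
#' @param x a PhasedGenotypes object.
#' @export
setMethod("sampleIds", "PhasedGenotypes", function(x) rownames(x@maternal))

#' @rdname PhasedGenotypes
#' @export
setMethod("markerMap", "PhasedGenotypes", function(x) x@map)

#' Maternal / paternal haplotype matrices
#' @param x a [PhasedGenotypes-class] object.
#' @return 0/1 matrix of alleles on the corresponding chromosome copy.
#' @export
maternalHaplotypes <- function(x) x@maternal

#' @rdname maternalHaplotypes
#' @export
paternalHaplotypes <- function(x) x@paternal

setMethod("show", "PhasedGenotypes", function(object) {
  cat("PhasedGenotypes:", nrow(object@maternal), "samples x",
      ncol(object@maternal), "markers (phase resolved)\n")
})
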