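#' @import methods
NULL

#' GenotypeData: biallelic SNP genotypes with a marker map
#'
#' Container for an n x p matrix of marker codes in \{0, 1, 2\} (count of the
#' counted allele per locus) together with a marker map giving chromosome and
#' physical position for every marker.  Fully homozygous (inbred / doubled
#' haploid) panels carry only codes 0 and 2; the `fullyHomozygous` flag is set
#' by scanning for code 1 at construction time.
#'
#' @slot codes integer/numeric matrix, n samples x p markers, entries in
#'   \{0, 1, 2\}; rownames are sample ids, colnames are marker ids.
#' @slot map data.frame with columns `marker_id`, `chrom`, `pos`, one row per
#'   marker, sorted by (chrom, pos).
#' @slot fullyHomozygous logical scalar, TRUE when no entry equals 1.
#'
#' @seealso [GenotypeData()] for the user-facing constructor,
#'   [readGenotypes()] for file input.
#' @export
setClass("GenotypeData",
  representation(
    codes = "matrix",
    map = "data.frame",
    fullyHomozygous = "logical"
  )
)

setValidity("GenotypeData", function(object) {
  msg <- character()
  cd <- object@codes
  if (!is.numeric(cd)) msg <- c(msg, "codes must be a numeric matrix")
  else if (length(cd) && !all(cd %in% c(0, 1, 2)))
    msg <- c(msg, "genotype codes must be 0, 1 or 2")
  if (!all(c("marker_id", "chrom", "pos") %in% names(object@map)))
    msg <- c(msg, "map must have columns marker_id, chrom, pos")
  else {
    if (nrow(object@map) != ncol(cd))
      msg <- c(msg, "map length must equal number of marker columns")
    if (anyDuplicated(object@map$marker_id))
      msg <- c(msg, "marker ids must be unique")
    if (any(object@map$pos < 0)) msg <- c(msg, "positions must be non-negative")
    o <- order(object@map$chrom, object@map$pos)
    if (!identical(o, seq_len(nrow(object@map))) &&
        is.unsorted(o))  # allow stable already-sorted maps
      msg <- c(msg, "markers must be sorted by (chrom, pos)")
  }
  if (is.null(rownames(cd)) && nrow(cd) > 0)
    msg <- c(msg, "codes must carry sample ids as rownames")
  else if (anyDuplicated(rownames(cd)))
    msg <- c(msg, "sample ids must be unique")
  if (length(object@fullyHomozygous) != 1)
    msg <- c(msg, "fullyHomozygous must be a single logical")
  else if (length(cd) && object@fullyHomozygous && any(cd == 1))
    msg <- c(msg, "fullyHomozygous panel contains a heterozygous code")
  if (length(msg)) msg else TRUE
})

#' PhasedGenotypes: maternal/paternal haplotypes per locus
#'
#' Two n x p matrices in \{0, 1\} holding the allele carried on each of the
#' two chromosome copies.  Their elementwise sum reproduces the \{0, 1, 2\}
#' codes of the [GenotypeData-class] they were derived from.
#'
#' @slot maternal,paternal 0/1 matrices, same dimnames.
#' @slot map marker map, as in [GenotypeData-class].
#' @export
setClass("PhasedGenotypes",
  representation(
    maternal = "matrix",
    paternal = "matrix",
    map = "data.frame"
  )
)

setValidity("PhasedGenotypes", function(object) {
  msg <- character()
  if (!identical(dim(object@maternal), dim(object@paternal)))
    msg <- c(msg, "maternal and paternal matrices must have equal dimensions")
  if (length(object@maternal) && !all(object@maternal %in% c(0, 1)))
    msg <- c(msg, "maternal entries must be 0/1")
  if (length(object@paternal) && !all(object@paternal %in% c(0, 1)))
    msg <- c(msg, "paternal entries must be 0/1")
  if (nrow(object@map) != ncol(object@maternal))
    msg <- c(msg, "map length must equal marker count")
  if (length(msg)) msg else TRUE
})

#' BlockPartition: non-overlapping fixed-length haplotype blocks
#'
#' Partition of the marker map into consecutive, non-overlapping blocks that
#' never span a chromosome boundary.  Marker index ranges are stored 1-based
#' and inclusive over columns of the genotype matrix.
#'
#' @slot blocks data.frame with columns `block_id`, `chrom`, `start`, `end`,
#'   `size` (number of markers).
#' @slot window the configured window length L.
#' @export
setClass("BlockPartition",
  representation(blocks = "data.frame", window = "numeric")
)

setValidity("BlockPartition", function(object) {
  b <- object@blocks
  msg <- character()
  need <- c("block_id", "chrom", "start", "end", "size")
  if (!all(need %in% names(b))) return("blocks table is missing columns")
  if (any(b$size < 1)) msg <- c(msg, "empty block")
  if (any(b$end - b$start + 1 != b$size)) msg <- c(msg, "size inconsistent with range")
  if (nrow(b) > 1) {
    same <- b$chrom[-1] == b$chrom[-nrow(b)]
    if (any(same & (b$start[-1] != b$end[-nrow(b)] + 1)))
      msg <- c(msg, "blocks must tile markers contiguously within chromosomes")
  }
  if (length(msg)) msg else TRUE
})

#' GenomicKernel: an n x n genomic relationship matrix
#'
#' Symmetric positive semi-definite relationship matrix with provenance
#' metadata (kernel kind, scaling constants, window length).
#'
#' @slot values symmetric n x n matrix with sample ids as dimnames.
#' @slot kind one of `"additive"`, `"haplotype"`, `"global_digenic"`,
#'   `"local_digenic"`, `"hadamard_power"`.
#' @slot meta list of scaling metadata (`p`, `q`, `w`, `window`, `t` as
#'   applicable).
#' @export
setClass("GenomicKernel",
  representation(values = "matrix", kind = "character", meta = "list")
)

setValidity("GenomicKernel", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "kernel must be square")
  else if (length(v) && max(abs(v - t(v))) > 1e-8 * (1 + max(abs(v))))
    msg <- c(msg, "kernel must be symmetric")
  kinds <- c("additive", "haplotype", "global_digenic", "local_digenic",
             "hadamard_power")
  if (length(object@kind) != 1 || !object@kind %in% kinds)
    msg <- c(msg, paste("kind must be one of:", paste(kinds, collapse = ", ")))
  if (length(msg)) msg else TRUE
})
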