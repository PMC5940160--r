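#' Genomic relationship (kernel) matrices
#'
#' Constructors for the relationship matrices used by the prediction models:
#' the additive kernel G1 = (1/p) M M', the haplotype kernel
#' H = (1/p) sum_k X_k X_k', the local digenic epistatic kernel
#' G2 = (1/2q) sum_k \[(M_k M_k') # (M_k M_k') - (M_k # M_k)(M_k # M_k)'\]
#' with q = sum_k p_k (p_k - 1) / 2 (`#` is the Hadamard, i.e. entrywise,
#' product), its genome-wide (global) counterpart, and entrywise powers of G1
#' for higher-order epistasis.  All kernels use the raw 0/1/2 allele counts,
#' without allele-frequency centering, so that the haplotype model and the
#' explicit local-epistasis marker model stay exactly linearly related; an
#' optional centering switch is provided for the additive kernel but is off
#' by default.  Note that the epistatic kernels depend on which allele is
#' counted.
#'
#' @param g a [GenotypeData-class] object.
#' @param center centre marker columns at their mean before forming G1
#'   (default FALSE).
#' @return a [GenomicKernel-class] object.
#' @name kernels
NULL

#' @rdname kernels
#' @export
additiveKernel <- function(g, center = FALSE) {
  M <- genoCodes(g)
  if (center) M <- sweep(M, 2, colMeans(M))
  K <- tcrossprod(M) / ncol(M)
  new("GenomicKernel", values = K, kind = "additive",
      meta = list(p = ncol(M), centered = center))
}

#' @rdname kernels
#' @param designs list of block designs from [enumerateBlockHaplotypes()].
#' @param p total marker count (the 1/p scaling of the haplotype kernel,
#'   under which the haplotype-effect and kernel formulations are equivalent
#'   with sigma_g^2 = p sigma_h^2).
#' @export
haplotypeKernel <- function(designs, p) {
  n <- nrow(designs[[1]]$X)
  K <- matrix(0, n, n)
  for (d in designs) {
    if (nrow(d$X) != n) stop("block designs disagree on sample count")
    K <- K + tcrossprod(d$X)
  }
  K <- K / p
  dimnames(K) <- dimnames(designs[[1]]$X)[c(1, 1)]
  new("GenomicKernel", values = K, kind = "haplotype",
      meta = list(p = p, w = length(designs)))
}

#' @rdname kernels
#' @param part a [BlockPartition-class] restricting epistasis to blocks.
#' @export
localDigenicKernel <- function(g, part) {
  M <- genoCodes(g)
  b <- blockTable(part)
  q <- sum(b$size * (b$size - 1)) / 2
  if (q == 0) stop("all blocks have a single marker: no local marker pairs")
  n <- nrow(M)
  K <- matrix(0, n, n)
  for (k in seq_len(nrow(b))) {
    if (b$size[k] < 2) next
    Mk <- M[, b$start[k]:b$end[k], drop = FALSE]
    A <- tcrossprod(Mk)
    K <- K + (A * A - tcrossprod(Mk * Mk))
  }
  K <- K / (2 * q)
  dimnames(K) <- list(rownames(M), rownames(M))
  new("GenomicKernel", values = K, kind = "local_digenic",
      meta = list(q = q, w = nrow(b), window = part@window))
}

#' @rdname kernels
#' @export
globalDigenicKernel <- function(g) {
  M <- genoCodes(g)
  p <- ncol(M)
  if (p < 2) stop("need at least two markers for digenic epistasis")
  q <- p * (p - 1) / 2
  A <- tcrossprod(M)
  K <- (A * A - tcrossprod(M * M)) / (2 * q)
  dimnames(K) <- list(rownames(M), rownames(M))
  new("GenomicKernel", values = K, kind = "global_digenic",
      meta = list(q = q, p = p))
}

#' @rdname kernels
#' @param G1 an additive [GenomicKernel-class].
#' @param t Hadamard power (t >= 2); the t-fold entrywise product of G1 is
#'   the kernel for (t-1)-th order additive-by-additive epistasis in the
#'   full local-epistasis model.
#' @export
hadamardPowerKernel <- function(G1, t) {
  stopifnot(t >= 2, t == round(t))
  K <- kernelValues(G1)^t
  new("GenomicKernel", values = K, kind = "hadamard_power",
      meta = c(kernelMeta(G1), list(t = t)))
}

#' @rdname GenomicKernel
#' @export
setMethod("kernelValues", "GenomicKernel", function(x) x@values)

#' @rdname GenomicKernel
#' @export
setMethod("kernelKind", "GenomicKernel", function(x) x@kind)

#' @rdname GenomicKernel
#' @export
setMethod("kernelMeta", "GenomicKernel", function(x) x@meta)

#' @rdname GenomicKernel
#' @export
setMethod("sampleIds", "GenomicKernel", function(x) rownames(x@values))

#' @rdname GenomicKernel
#' @export
setMethod("nSamples", "GenomicKernel", function(x) nrow(x@values))

setMethod("show", "GenomicKernel", function(object) {
  cat("GenomicKernel (", object@kind, "): ", nrow(object@values), " x ",
      ncol(object@values), "\n", sep = "")
  m <- object@meta
  if (length(m))
    cat("  meta:", paste(names(m), unlist(m), sep = "=", collapse = ", "),
        "\n")
})

#' Export / import a kernel with a metadata sidecar
#'
#' The kernel is written as a TSV with a header row of sample ids; the
#' sidecar (`<path>.meta.json`) records kind and scaling metadata.
#'
#' @param k a [GenomicKernel-class] object.
#' @param path file to write / read.
#' @export
writeKernel <- function(k, path) {
  utils::write.table(kernelValues(k), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  jsonlite::write_json(c(list(kind = kernelKind(k)), kernelMeta(k)),
                       paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeKernel
#' @export
readKernel <- function(path) {
  v <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  rownames(v) <- colnames(v)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  new("GenomicKernel", values = v, kind = meta$kind,
      meta = meta[setdiff(names(meta), "kind")])
}

# Convenience: haplotype kernel straight from genotypes + window length.
#' @rdname kernels
#' @param window fixed block length L for the haplotype kernel.
#' @param phased optional pre-phased genotypes for heterozygous panels.
#' @param seed phase-assignment seed when `g` is heterozygous and no phasing
#'   is supplied.
#' @export
haplotypeKernelFromGenotypes <- function(g, window, phased = NULL,
                                         seed = NULL) {
  part <- partitionFixedWindows(markerMap(g), window)
  src <- if (!is.null(phased)) phased
         else if (isFullyHomozygous(g)) g
         else assignRandomPhase(g, seed)
  haplotypeKernel(enumerateBlockHaplotypes(src, part), nMarkers(g))
}
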