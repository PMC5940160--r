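#' Partition the marker map into fixed-length haplotype blocks
#'
#' Consecutive runs of `window` markers per chromosome form the blocks; a
#' trailing run of fewer than `window` markers at a chromosome end is kept as
#' its own (shorter) block.  Blocks are non-overlapping, jointly cover all
#' markers and never span a chromosome boundary.
#'
#' @param map marker map data.frame (`marker_id`, `chrom`, `pos`), sorted by
#'   (chrom, pos), or a [GenotypeData-class] object.
#' @param window block length L (number of SNPs), L >= 1.
#' @return a [BlockPartition-class] object.
#' @examples
#' map <- data.frame(marker_id = paste0("m", 1:10), chrom = "1", pos = 1:10)
#' blockTable(partitionFixedWindows(map, 3))$size
#' @export
partitionFixedWindows <- function(map, window) {
  if (is(map, "GenotypeData")) map <- markerMap(map)
  if (nrow(map) == 0) stop("empty marker map")
  stopifnot(window >= 1)
  chroms <- rle(as.character(map$chrom))
  starts <- cumsum(c(1, chroms$lengths[-length(chroms$lengths)]))
  rows <- list()
  for (i in seq_along(chroms$values)) {
    n <- chroms$lengths[i]
    bs <- seq(1, n, by = window)
    be <- pmin(bs + window - 1, n)
    rows[[i]] <- data.frame(chrom = chroms$values[i],
                            start = starts[i] + bs - 1,
                            end = starts[i] + be - 1)
  }
  b <- do.call(rbind, rows)
  b$size <- b$end - b$start + 1
  b <- data.frame(block_id = paste0("b", seq_len(nrow(b))), b)
  new("BlockPartition", blocks = b, window = window)
}

#' @rdname BlockPartition
#' @export
setMethod("blockTable", "BlockPartition", function(x) x@blocks)

#' @rdname BlockPartition
#' @export
setMethod("nBlocks", "BlockPartition", function(x) nrow(x@blocks))

setMethod("show", "BlockPartition", function(object) {
  cat("BlockPartition:", nrow(object@blocks), "blocks, window L =",
      object@window, "\n")
  cat("  block sizes:", paste(range(object@blocks$size), collapse = "-"), "\n")
})

#' Export a block partition as a BED-like table
#'
#' @param part a [BlockPartition-class] object.
#' @param path optional file to write (tab-separated, no header).
#' @return data.frame with columns chrom, start_marker_index,
#'   end_marker_index, block_id (marker indices, 1-based inclusive).
#' @export
exportPartition <- function(part, path = NULL) {
  b <- blockTable(part)
  out <- data.frame(chrom = b$chrom, start_marker_index = b$start,
                    end_marker_index = b$end, block_id = b$block_id)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  out
}

#' Enumerate haplotype alleles and build block design matrices
#'
#' For every block, the distinct haplotype strings observed among the 2n
#' chromosome copies are enumerated (lexicographic order) and the n x s_k
#' design matrix X_k counts, for each individual, how many of its two copies
#' carry each allele.  Every row of X_k sums to 2; for fully homozygous data
#' the entries are 0/2 with exactly one nonzero per row.
#'
#' @param phased a [PhasedGenotypes-class] object (use [assignRandomPhase()]
#'   for unknown-phase panels; for fully homozygous panels a
#'   [GenotypeData-class] object is accepted directly).
#' @param part a [BlockPartition-class] object.
#' @return list with one element per block: `list(alleles, X)` where
#'   `alleles` is the character vector of haplotype strings and `X` the
#'   n x s_k count matrix (columns named by allele).
#' @export
enumerateBlockHaplotypes <- function(phased, part) {
  if (is(phased, "GenotypeData")) {
    if (!isFullyHomozygous(phased))
      stop("heterozygous panel: resolve phase first (assignRandomPhase)")
    h <- genoCodes(phased) / 2
    phased <- PhasedGenotypes(h, h, markerMap(phased))
  }
  mat <- maternalHaplotypes(phased)
  pat <- paternalHaplotypes(phased)
  b <- blockTable(part)
  lapply(seq_len(nrow(b)), function(k) {
    idx <- b$start[k]:b$end[k]
    s1 <- hapStrings(mat[, idx, drop = FALSE])
    s2 <- hapStrings(pat[, idx, drop = FALSE])
    alleles <- sort(unique(c(s1, s2)))
    X <- (outer(s1, alleles, "==") + outer(s2, alleles, "==")) * 1
    dimnames(X) <- list(rownames(mat), alleles)
    list(alleles = alleles, X = X, block_id = b$block_id[k])
  })
}

#' Drop the redundant haplotype-allele column of a block design
#'
#' Because every row of X_k sums to 2, one allele column is a linear
#' combination of the others and the all-ones vector, so it carries no
#' independent information.  Allele columns are re-ordered by decreasing
#' haplotype string (so the all-carrier haplotype comes first) and the last
#' one -- the all-zero-code haplotype whenever it is observed -- is removed.
#' Used by the transform machinery only; kernel construction always keeps
#' the full allele set.
#'
#' @param d one block design as returned by [enumerateBlockHaplotypes()].
#' @return the design with one fewer allele column.
#' @export
dropRedundantAllele <- function(d) {
  if (length(d$alleles) < 2)
    stop("monomorphic block: only one haplotype allele observed")
  ord <- order(d$alleles, decreasing = TRUE)
  keep <- ord[seq_len(length(ord) - 1)]
  list(alleles = d$alleles[keep], X = d$X[, keep, drop = FALSE],
       dropped = d$alleles[ord[length(ord)]], block_id = d$block_id)
}
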