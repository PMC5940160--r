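# Fixtures built in code: the two worked 2-SNP example panels and random
# small panels used by the oracle/property tests.

twoSnpMap <- function() {
  data.frame(marker_id = c("SNP1", "SNP2"), chrom = "1", pos = c(100, 200))
}

# Six inbred individuals, one 2-SNP block; haplotype alleles 11,10,01,00.
inbredExamplePanel <- function() {
  GenotypeData(matrix(c(2, 2, 2, 0, 0, 2, 0, 0, 2, 0, 2, 2),
                      ncol = 2, byrow = TRUE), twoSnpMap())
}

# Same block with heterozygotes; phases as listed (individual 6 = 10/01).
hetExamplePhased <- function() {
  mat <- matrix(c(1, 1, 1, 0, 0, 1, 1, 1, 1, 0, 1, 0), ncol = 2, byrow = TRUE)
  pat <- matrix(c(1, 1, 1, 0, 0, 1, 1, 0, 0, 0, 0, 1), ncol = 2, byrow = TRUE)
  rownames(mat) <- paste0("ind", 1:6)
  PhasedGenotypes(mat, pat, twoSnpMap())
}

hetExamplePanel <- function() {
  ph <- hetExamplePhased()
  GenotypeData(maternalHaplotypes(ph) + paternalHaplotypes(ph), twoSnpMap())
}

# Random fully homozygous panel on a single chromosome.
randomInbredPanel <- function(n, p, seed = NULL) {
  codes <- hgblup:::withSeed(seed,
    matrix(2 * rbinom(n * p, 1, 0.5), n, p))
  GenotypeData(codes, data.frame(marker_id = paste0("m", seq_len(p)),
                                 chrom = "1", pos = seq_len(p)))
}

# Brute-force digenic epistatic design: one column per within-block marker
# pair (i < j), entries = elementwise product of the code columns.
pairwiseDesign <- function(M, blocks) {
  cols <- list()
  for (idx in blocks) {
    if (length(idx) < 2) next
    for (co in utils::combn(idx, 2, simplify = FALSE))
      cols[[length(cols) + 1]] <- M[, co[1]] * M[, co[2]]
  }
  unname(do.call(cbind, cols))
}

blocksOfPartition <- function(part) {
  b <- blockTable(part)
  lapply(seq_len(nrow(b)), function(k) b$start[k]:b$end[k])
}

expect_psd <- function(K, tol = 1e-8) {
  v <- if (is(K, "GenomicKernel")) kernelValues(K) else K
  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -tol * max(abs(ev), 1))
}
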