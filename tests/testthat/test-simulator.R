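test_that("genotype simulation is reproducible, inbred and polymorphic", {
  g1 <- simulateInbredGenotypes(50, nChrom = 3, markersPerChrom = 40,
                                seed = 1)
  g2 <- simulateInbredGenotypes(50, nChrom = 3, markersPerChrom = 40,
                                seed = 1)
  expect_identical(genoCodes(g1), genoCodes(g2))
  g3 <- simulateInbredGenotypes(50, nChrom = 3, markersPerChrom = 40,
                                seed = 2)
  expect_false(identical(genoCodes(g1), genoCodes(g3)))
  expect_true(all(genoCodes(g1) %in% c(0, 2)))
  expect_true(isFullyHomozygous(g1))
  expect_true(all(apply(genoCodes(g1), 2, var) > 0))  # no monomorphic marker
  expect_equal(length(unique(markerMap(g1)$chrom)), 3)
})

test_that("linkage between adjacent markers weakens with the crossover rate", {
  adjCor <- function(rate) {
    g <- simulateInbredGenotypes(200, nChrom = 1, markersPerChrom = 300,
                                 recombRate = rate, seed = 3)
    M <- genoCodes(g)
    mean(sapply(1:299, function(j) cor(M[, j], M[, j + 1])^2))
  }
  expect_gt(adjCor(0.02), adjCor(0.5) + 0.05)
})

test_that("QTL sampling matches the per-chromosome design", {
  g <- simulateInbredGenotypes(30, nChrom = 5, markersPerChrom = 30, seed = 4)
  spec <- scenarioSpec(1, nQtlPerChrom = 20)
  q <- sampleQtl(g, spec, seed = 5)
  expect_length(q$qtl, 100)
  expect_true(all(table(markerMap(g)$chrom[q$qtl]) == 20))
  expect_false(anyDuplicated(q$qtl) > 0)

  # all markers become QTL when the counts coincide
  specAll <- scenarioSpec(1, nQtlPerChrom = 30)
  expect_identical(sampleQtl(g, specAll, seed = 6)$qtl, seq_len(150))
  expect_error(sampleQtl(g, scenarioSpec(1, nQtlPerChrom = 31), seed = 1),
               "fewer")

  # scenario 2: distinct unordered pairs
  sp2 <- scenarioSpec(2, nQtlPerChrom = 20, nGlobalPairs = 50)
  q2 <- sampleQtl(g, sp2, seed = 7)
  expect_equal(dim(q2$pairs), c(50, 2))
  expect_true(all(q2$pairs[, 1] < q2$pairs[, 2]))
  expect_false(anyDuplicated(paste(q2$pairs[, 1], q2$pairs[, 2])) > 0)
})

test_that("QTL blocks have sizes 2..(max+1) and conserve the QTL", {
  g <- simulateInbredGenotypes(10, nChrom = 2, markersPerChrom = 120, seed = 8)
  spec <- scenarioSpec(5, nQtlPerChrom = 100)
  q <- sampleQtl(g, spec, seed = 9)
  blocks <- partitionQtlBlocks(q$qtl, markerMap(g), spec, seed = 10)
  sizes <- lengths(blocks)
  expect_true(all(sizes >= 2 & sizes <= 6))  # 2..5 runs, trailing 1 merged
  expect_identical(sort(unlist(blocks)), q$qtl)
  expect_identical(partitionQtlBlocks(q$qtl, markerMap(g), spec, seed = 10),
                   blocks)
  # expected run length 3.5 => roughly n/3.5 blocks
  expect_gt(length(blocks), 200 / 3.5 * 0.7)
  expect_lt(length(blocks), 200 / 3.5 * 1.4)
})

test_that("effect patterns follow the scenario definitions", {
  g <- simulateInbredGenotypes(20, nChrom = 2, markersPerChrom = 30, seed = 11)
  q1 <- sampleQtl(g, scenarioSpec(1, nQtlPerChrom = 10), seed = 12)
  e1 <- drawEffects(scenarioSpec(1, nQtlPerChrom = 10), q1, seed = 13)
  expect_length(e1$additive, 20)
  expect_null(e1$pairEffects)
  expect_null(e1$blockEffects)

  # correlated local scenarios carry the canonical covariance
  sp6 <- scenarioSpec(6, nQtlPerChrom = 10)
  q6 <- sampleQtl(g, sp6, seed = 14)
  b6 <- partitionQtlBlocks(q6$qtl, markerMap(g), sp6, seed = 15)
  e6 <- drawEffects(sp6, q6, b6, seed = 16)
  be <- e6$blockEffects[[which(lengths(lapply(e6$blockEffects, `[[`,
                                              "markers")) == 2)[1]]]
  ord <- lengths(be$subsets)
  expect_equal(diag(be$cov)[ord == 2], 3 / 4, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(be$cov[ord == 2, ord == 1][1] /
                 sqrt(be$cov[1, 1] * diag(be$cov)[ord == 2]),
               -1 / sqrt(3), tolerance = 1e-10, ignore_attr = TRUE)

  # 3:1 ratio: digenic variance sigma_a^2 / 3, correlations preserved
  sp63 <- scenarioSpec(6, ratio = c(3, 1), nQtlPerChrom = 10)
  e63 <- drawEffects(sp63, q6, b6, seed = 16)
  be3 <- e63$blockEffects[[1]]
  ord3 <- lengths(be3$subsets)
  expect_equal(unname(diag(be3$cov)[ord3 == 2]),
               rep(1 / 3, sum(ord3 == 2)), tolerance = 1e-10)
  expect_lt(max(abs(cov2cor(unclass(be3$cov)) -
                      cov2cor(unclass(e6$blockEffects[[1]]$cov)))), 1e-10)

  # digenic-only scenarios truncate the order-3+ rows/columns
  sp5 <- scenarioSpec(5, nQtlPerChrom = 10)
  e5 <- drawEffects(sp5, q6, b6, seed = 16)
  k <- which(lengths(lapply(e6$blockEffects, `[[`, "markers")) >= 3)[1]
  ord6k <- lengths(e6$blockEffects[[k]]$subsets)
  expect_lt(max(abs(e5$blockEffects[[k]]$cov -
                      e6$blockEffects[[k]]$cov[ord6k <= 2, ord6k <= 2])),
            1e-12)

  # independent scenarios share the variance profile but not the covariances
  e4 <- drawEffects(scenarioSpec(4, nQtlPerChrom = 10), q6, b6, seed = 17)
  cv4 <- e4$blockEffects[[k]]$cov
  expect_equal(unname(diag(cv4)), unname(diag(e6$blockEffects[[k]]$cov)),
               tolerance = 1e-10)
  expect_equal(unname(cv4[lower.tri(cv4)]),
               rep(0, sum(lower.tri(cv4))))
})

test_that("genetic values are the exact design-matrix combinations", {
  g <- randomInbredPanel(5, 6, seed = 18)
  M <- genoCodes(g)
  spec <- scenarioSpec(1, nQtlPerChrom = 1)
  qtl <- list(qtl = 4L)
  expect_equal(unname(geneticValues(g, qtl, list(additive = 1), spec)),
               unname(M[, 4]))
  expect_equal(unname(geneticValues(g, qtl, list(additive = 0), spec)),
               rep(0, 5))
  expect_error(geneticValues(g, qtl, list(additive = c(1, 2)), spec),
               "match")

  # scenario 3: brute-force additive + pairwise sum over one block
  sp3 <- scenarioSpec(3, nQtlPerChrom = 3)
  blocks <- list(c(1L, 3L, 5L))
  cv <- truncateCovariance(blockEffectCovariance(3), 2)
  eff <- list(blockEffects = list(list(markers = blocks[[1]],
                                       subsets = attr(cv, "subsets"),
                                       effects = c(1, -2, 0.5, 2, -1, 3),
                                       cov = cv)))
  gv <- geneticValues(g, list(qtl = blocks[[1]]), eff, sp3)
  manual <- 1 * M[, 1] - 2 * M[, 3] + 0.5 * M[, 5] +
    2 * M[, 1] * M[, 3] - 1 * M[, 1] * M[, 5] + 3 * M[, 3] * M[, 5]
  expect_equal(unname(gv), unname(manual))
})

test_that("phenotype noise follows the heritability formula", {
  set.seed(19)
  gv <- rnorm(2000, 0, sqrt(2))
  expect_identical(simulatePhenotype(gv, h2 = 1), gv)
  y <- simulatePhenotype(gv, h2 = 0.5, seed = 20)
  e <- y - gv
  # sigma_e^2 = (1 - h2)/h2 * var(g) = var(g); chi-square CI at n = 2000
  expect_lt(abs(var(e) / var(gv) - 1), 0.15)
  expect_error(simulatePhenotype(rep(1, 10), 0.5), "constant")

  # realized heritability centred at the target
  g <- simulateInbredGenotypes(500, nChrom = 5, markersPerChrom = 60,
                               seed = 21)
  h2s <- sapply(1:10, function(r)
    simulateTrait(g, scenarioSpec(1, h2 = 0.7, nQtlPerChrom = 40),
                  seed = 100 + r)$realizedH2)
  expect_equal(t.test(h2s, mu = 0.7)$p.value > 0.01, TRUE)
})

test_that("trait replicates are reproducible end to end", {
  g <- simulateInbredGenotypes(40, nChrom = 2, markersPerChrom = 40, seed = 22)
  spec <- scenarioSpec(6, h2 = 0.5, nQtlPerChrom = 20)
  t1 <- simulateTrait(g, spec, seed = 23)
  t2 <- simulateTrait(g, spec, seed = 23)
  expect_identical(t1$y, t2$y)
  expect_identical(t1$effects, t2$effects)
  expect_false(identical(t1$y, simulateTrait(g, spec, seed = 24)$y))
  # y - g is exactly the drawn error, with variance tied to var(g)
  expect_equal(var(t1$g) / var(t1$y), t1$realizedH2, tolerance = 1e-12)
})
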