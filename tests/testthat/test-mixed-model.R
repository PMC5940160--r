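# Mixed-model equation (ridge) oracle with per-effect penalties, fitted on
# the observed individuals and evaluated on all rows of Wall.
ridgeOracle <- function(y, W, lambda, Wall = W) {
  A <- rbind(c(length(y), colSums(W)),
             cbind(colSums(W), crossprod(W) + diag(lambda, ncol(W))))
  sol <- unname(solve(A, c(sum(y), drop(crossprod(W, y)))))
  list(mu = sol[1], g = drop(Wall %*% sol[-1]))
}

test_that("a single identity kernel shrinks by the ridge factor", {
  set.seed(1)
  n <- 30
  y <- rnorm(n); names(y) <- paste0("i", 1:n)
  K <- diag(n); dimnames(K) <- list(names(y), names(y))
  for (sg2 in c(0.5, 1, 3)) {
    f <- fitKernelModel(y, K, varComp = c(sg2, 1))
    expect_equal(unname(f$totalGHat), sg2 / (sg2 + 1) * (y - f$mu),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("REML interpolates noiseless phenotypes", {
  g <- simulateInbredGenotypes(80, nChrom = 3, markersPerChrom = 60, seed = 2)
  tr <- simulateTrait(g, scenarioSpec(1, h2 = 1, nQtlPerChrom = 30), seed = 3)
  fit <- fitKernelModel(tr$y, additiveKernel(g))
  expect_gt(cor(fit$totalGHat, tr$y - fit$mu), 0.999)
  expect_lt(fit$varComp["error"] / sum(fit$varComp), 0.01)
})

test_that("kernel GBLUP equals ridge regression on marker effects", {
  g <- randomInbredPanel(25, 40, seed = 4)
  M <- genoCodes(g)
  set.seed(5)
  y <- drop(M %*% rnorm(40, 0, 0.3)) + rnorm(25)
  names(y) <- sampleIds(g)
  sa2 <- 0.2; se2 <- 1.5
  fit <- fitKernelModel(y, additiveKernel(g), varComp = c(40 * sa2, se2))
  orc <- ridgeOracle(y, M, rep(se2 / sa2, 40))
  expect_equal(unname(fit$totalGHat), orc$g, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(fit$mu, orc$mu, tolerance = 1e-6)
})

test_that("haplotype-effect ridge and haplotype-kernel fits coincide", {
  # explicit haplotype effects with variance sh2 <-> kernel H with p * sh2
  g <- randomInbredPanel(30, 12, seed = 6)
  part <- partitionFixedWindows(markerMap(g), 3)
  des <- enumerateBlockHaplotypes(g, part)
  X <- do.call(cbind, lapply(des, `[[`, "X"))
  set.seed(7)
  y <- rnorm(30) + drop(X %*% rnorm(ncol(X), 0, 0.5))
  names(y) <- sampleIds(g)
  sh2 <- 0.4; se2 <- 1
  H <- haplotypeKernel(des, nMarkers(g))
  fit <- fitKernelModel(y, H, varComp = c(nMarkers(g) * sh2, se2))
  orc <- ridgeOracle(y, X, rep(se2 / sh2, ncol(X)))
  expect_equal(unname(fit$totalGHat), orc$g, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("additive+digenic ridge and two-kernel fits coincide", {
  g <- randomInbredPanel(30, 12, seed = 8)
  part <- partitionFixedWindows(markerMap(g), 3)
  M <- genoCodes(g)
  F_ <- pairwiseDesign(M, blocksOfPartition(part))
  q <- ncol(F_)
  set.seed(9)
  y <- rnorm(30) + drop(M %*% rnorm(ncol(M), 0, 0.4)) +
    drop(F_ %*% rnorm(q, 0, 0.2))
  names(y) <- sampleIds(g)
  sa2 <- 0.3; saa2 <- 0.1; se2 <- 1
  ks <- list(additiveKernel(g), localDigenicKernel(g, part))
  fit <- fitKernelModel(y, ks, varComp = c(ncol(M) * sa2, q * saa2, se2))
  orc <- ridgeOracle(y, cbind(M, F_),
                     c(rep(se2 / sa2, ncol(M)), rep(se2 / saa2, q)))
  expect_equal(unname(fit$totalGHat), orc$g, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("BLUP prediction honors kernel structure for held-out samples", {
  g <- randomInbredPanel(20, 15, seed = 10)
  codes <- genoCodes(g)
  codes[20, ] <- codes[1, ]        # test individual clones training ind 1
  codes[19, ] <- 0                 # unrelated under the raw-code kernel
  g <- GenotypeData(codes, markerMap(g))
  set.seed(11)
  y <- rnorm(20); names(y) <- sampleIds(g)
  y[19:20] <- NA
  fit <- fitKernelModel(y, additiveKernel(g), varComp = c(1, 1))
  expect_equal(fit$totalGHat[["ind20"]], fit$totalGHat[["ind1"]],
               tolerance = 1e-8)
  expect_equal(fit$totalGHat[["ind19"]], 0, tolerance = 1e-10)
  expect_equal(unname(predictGenetic(fit, c("ind19", "ind20"))),
               unname(fit$totalGHat[19:20]))
  expect_error(predictGenetic(fit, "nobody"), "absent")
})

test_that("masking an individual of a noiseless trait recovers its value", {
  g <- simulateInbredGenotypes(100, nChrom = 4, markersPerChrom = 50,
                               seed = 12)
  tr <- simulateTrait(g, scenarioSpec(1, h2 = 1, nQtlPerChrom = 25),
                      seed = 13)
  y <- tr$y
  mask <- c(3, 20, 47, 66, 91)
  y[mask] <- NA
  fit <- fitKernelModel(y, additiveKernel(g))
  expect_gt(cor(fit$totalGHat[mask], tr$g[mask]), 0.8)
})

test_that("REML recovers known variance components on average", {
  g <- simulateInbredGenotypes(150, nChrom = 4, markersPerChrom = 60,
                               seed = 14)
  part <- partitionFixedWindows(markerMap(g), 3)
  K1 <- hgblup:::addJitter(kernelValues(additiveKernel(g)))
  K2 <- hgblup:::addJitter(kernelValues(localDigenicKernel(g, part)))
  L1 <- chol(K1); L2 <- chol(K2)
  true <- c(2, 1, 1)
  set.seed(15)
  est <- replicate(30, {
    y <- sqrt(true[1]) * drop(crossprod(L1, rnorm(150))) +
      sqrt(true[2]) * drop(crossprod(L2, rnorm(150))) +
      rnorm(150, 0, sqrt(true[3]))
    names(y) <- sampleIds(g)
    fitKernelModel(y, list(K1, K2))$varComp
  })
  m <- rowMeans(est)
  expect_lt(abs(m[1] - true[1]), 0.5)
  expect_lt(abs(m[2] - true[2]), 0.4)
  expect_lt(abs(m[3] - true[3]), 0.3)
})

test_that("the Gibbs sampler agrees with REML and is seed-reproducible", {
  g <- simulateInbredGenotypes(100, nChrom = 3, markersPerChrom = 50,
                               seed = 16)
  tr <- simulateTrait(g, scenarioSpec(1, h2 = 0.7, nQtlPerChrom = 25),
                      seed = 17)
  K <- additiveKernel(g)
  fr <- fitKernelModel(tr$y, K)
  fg <- fitKernelModel(tr$y, K, method = "gibbs", burnin = 200, iter = 400,
                       seed = 18)
  expect_gt(cor(fg$totalGHat, fr$totalGHat), 0.95)
  expect_true(all(fg$varComp > 0))
  fg2 <- fitKernelModel(tr$y, K, method = "gibbs", burnin = 200, iter = 400,
                        seed = 18)
  expect_identical(fg$varComp, fg2$varComp)
})

test_that("degenerate inputs are rejected cleanly", {
  y <- c(a = 1, b = 2, c = 3)
  expect_error(fitKernelModel(y, -diag(3)), "positive semi-definite")
  expect_error(fitKernelModel(c(a = 1, b = NA, c = NA), diag(3)),
               "at least two")
  expect_error(fitKernelModel(y, diag(4)), "does not match")
})
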