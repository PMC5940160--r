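#' Specify a trait simulation scenario
#'
#' Six architectures of QTL effects are supported, differing in the type
#' (none / global / local), order (digenic only / all orders) and pattern
#' (independent / correlated) of epistasis:
#' \describe{
#'   \item{1}{additive effects only, independent.}
#'   \item{2}{additive + global digenic epistasis among random marker pairs,
#'     independent.}
#'   \item{3}{additive + local digenic epistasis inside QTL blocks,
#'     independent.}
#'   \item{4}{additive + local digenic and higher-order epistasis,
#'     independent (variances follow the canonical per-order profile).}
#'   \item{5}{as 3, but per-block effects drawn jointly with the correlated
#'     covariance implied by the haplotype model, truncated to digenic
#'     terms.}
#'   \item{6}{as 4, with the full correlated covariance V V' sigma_h^2.}
#' }
#'
#' The additive variance is fixed at `sigmaA2` (default 1; only ratios
#' matter once the error variance is tied to the heritability) and the
#' additive : digenic ratio is `ratio` (the canonical covariance gives 4:3;
#' 3:1 weakens epistasis via [adjustVarianceRatio()]).
#'
#' @param scenario integer 1-6.
#' @param h2 target heritability in (0, 1].
#' @param ratio numeric pair, additive : digenic variance ratio.
#' @param nQtlPerChrom QTL sampled per chromosome (default 100).
#' @param nGlobalPairs number of epistatic marker pairs in scenario 2.
#' @param blockSizeRange QTL block length range for scenarios 3-6.
#' @param sigmaA2 additive effect variance.
#' @return object of class `hgblup_scenario`.
#' @export
scenarioSpec <- function(scenario, h2 = 0.7, ratio = c(4, 3),
                         nQtlPerChrom = 100, nGlobalPairs = 1000,
                         blockSizeRange = c(2, 5), sigmaA2 = 1) {
  stopifnot(scenario %in% 1:6, h2 > 0, h2 <= 1,
            length(ratio) == 2, all(ratio > 0),
            nQtlPerChrom >= 1, blockSizeRange[1] >= 2,
            blockSizeRange[2] >= blockSizeRange[1], sigmaA2 > 0)
  structure(list(scenario = as.integer(scenario), h2 = h2, ratio = ratio,
                 nQtlPerChrom = as.integer(nQtlPerChrom),
                 nGlobalPairs = as.integer(nGlobalPairs),
                 blockSizeRange = as.integer(blockSizeRange),
                 sigmaA2 = sigmaA2),
            class = "hgblup_scenario")
}

#' Simulate a fully homozygous (inbred) genotype panel
#'
#' Founder-mosaic model: per chromosome, `nFounders` random founder
#' haplotypes are drawn and each individual's single (doubled) haplotype is
#' a crossover mosaic of them, with geometric segment lengths governed by
#' `recombRate` (per marker interval).  This produces blocks of correlated
#' markers -- the linkage structure haplotype methods rely on -- with all
#' codes in \{0, 2\}.  Monomorphic markers are re-drawn.
#'
#' @param n number of individuals.
#' @param nChrom number of chromosomes (default 10).
#' @param markersPerChrom markers per chromosome.
#' @param nFounders founder haplotypes per chromosome (default 8).
#' @param recombRate probability of a crossover between adjacent markers.
#' @param seed RNG seed.
#' @return a [GenotypeData-class] panel with `isFullyHomozygous(x) == TRUE`.
#' @export
simulateInbredGenotypes <- function(n, nChrom = 10, markersPerChrom = 300,
                                    nFounders = 8, recombRate = 0.05,
                                    seed = NULL) {
  stopifnot(nFounders >= 2, n >= 1, markersPerChrom >= 1)
  withSeed(seed, {
    hapList <- vector("list", nChrom)
    for (cc in seq_len(nChrom)) {
      m <- markersPerChrom
      fnd <- matrix(stats::rbinom(nFounders * m, 1, 0.5), nFounders, m)
      A <- matrix(0L, n, m)
      for (i in seq_len(n)) {
        cuts <- if (m > 1) which(stats::rbinom(m - 1, 1, recombRate) == 1)
                else integer(0)
        segLen <- diff(c(0, cuts, m))
        A[i, ] <- rep(sample.int(nFounders, length(segLen), replace = TRUE),
                      segLen)
      }
      hap <- matrix(fnd[cbind(c(A), rep(seq_len(m), each = n))], n, m)
      # re-draw founder alleles at monomorphic markers
      for (j in which(apply(hap, 2, function(x) length(unique(x)) == 1))) {
        for (try_ in 1:20) {
          fnd[, j] <- stats::rbinom(nFounders, 1, 0.5)
          hap[, j] <- fnd[A[, j], j]
          if (length(unique(hap[, j])) > 1) break
        }
        if (length(unique(hap[, j])) == 1) {
          fnd[, j] <- rep_len(c(0, 1), nFounders)
          hap[, j] <- fnd[A[, j], j]
        }
      }
      hapList[[cc]] <- hap
    }
    codes <- 2 * do.call(cbind, hapList)
    map <- data.frame(
      marker_id = paste0("c", rep(seq_len(nChrom), each = markersPerChrom),
                         "_m", rep(seq_len(markersPerChrom), nChrom)),
      chrom = as.character(rep(seq_len(nChrom), each = markersPerChrom)),
      pos = rep(seq_len(markersPerChrom) * 1000L, nChrom))
    GenotypeData(codes, map)
  })
}

#' Sample QTL positions (and epistatic pairs) for a scenario
#'
#' Uniform sampling without replacement of `nQtlPerChrom` markers per
#' chromosome; scenario 2 additionally samples `nGlobalPairs` distinct
#' unordered QTL pairs genome-wide.
#'
#' @param g a [GenotypeData-class] panel.
#' @param spec a [scenarioSpec()].
#' @param seed RNG seed.
#' @return list with `qtl` (sorted marker indices) and, for scenario 2,
#'   `pairs` (two-column index matrix).
#' @export
sampleQtl <- function(g, spec, seed = NULL) {
  map <- markerMap(g)
  withSeed(seed, {
    qtl <- unlist(lapply(split(seq_len(nrow(map)), map$chrom), function(idx) {
      if (length(idx) < spec$nQtlPerChrom)
        stop("chromosome has ", length(idx), " markers, fewer than ",
             spec$nQtlPerChrom, " QTL requested")
      sort(sample(idx, spec$nQtlPerChrom))
    }), use.names = FALSE)
    qtl <- sort(qtl)
    pairs <- NULL
    if (spec$scenario == 2L) {
      npos <- length(qtl) * (length(qtl) - 1) / 2
      if (spec$nGlobalPairs > npos)
        stop("cannot sample ", spec$nGlobalPairs, " distinct pairs from ",
             length(qtl), " QTL")
      seen <- character(0)
      pairs <- matrix(0L, spec$nGlobalPairs, 2)
      k <- 0L
      while (k < spec$nGlobalPairs) {
        cand <- sort(sample(qtl, 2))
        key <- paste(cand, collapse = "_")
        if (!key %in% seen) {
          k <- k + 1L
          pairs[k, ] <- cand
          seen <- c(seen, key)
        }
      }
    }
    list(qtl = qtl, pairs = pairs)
  })
}

#' Group the sampled QTL of each chromosome into epistatic blocks
#'
#' Consecutive QTL are grouped into runs of random length drawn uniformly
#' from `blockSizeRange`; a trailing run of a single QTL (which admits no
#' local epistasis) is merged into the previous block.
#'
#' @param qtl sorted QTL marker indices.
#' @param map marker map of the panel.
#' @param spec a [scenarioSpec()].
#' @param seed RNG seed.
#' @return list of integer vectors, one block of marker indices each.
#' @export
partitionQtlBlocks <- function(qtl, map, spec, seed = NULL) {
  lo <- spec$blockSizeRange[1]; hi <- spec$blockSizeRange[2]
  withSeed(seed, {
    out <- list()
    for (idx in split(qtl, map$chrom[qtl])) {
      n <- length(idx)
      sizes <- integer(0)
      left <- n
      while (left > 0) {
        s <- min(sample(lo:hi, 1), left)
        sizes <- c(sizes, s)
        left <- left - s
      }
      if (length(sizes) > 1 && sizes[length(sizes)] == 1) {
        sizes[length(sizes) - 1] <- sizes[length(sizes) - 1] + 1
        sizes <- sizes[-length(sizes)]
      }
      ends <- cumsum(sizes)
      starts <- c(1, ends[-length(ends)] + 1)
      out <- c(out, lapply(seq_along(sizes),
                           function(k) idx[starts[k]:ends[k]]))
    }
    out
  })
}

#' Draw QTL effects under a scenario
#'
#' Scenario 1 draws iid additive effects; scenario 2 adds iid digenic
#' effects for the global pairs (variance sigma_a^2 * re/ra); scenarios 3-6
#' draw per-block effect vectors over marker subsets, independent (3, 4,
#' using the diagonal of the canonical covariance) or jointly correlated
#' (5, 6, using the full covariance from [blockEffectCovariance()], adjusted
#' to the requested variance ratio, and truncated to digenic terms for
#' scenarios 3 and 5).
#'
#' @param spec a [scenarioSpec()].
#' @param qtl result of [sampleQtl()].
#' @param blocks result of [partitionQtlBlocks()] (scenarios 3-6).
#' @param seed RNG seed.
#' @return list with `additive` and `pairEffects` (scenarios 1-2) or
#'   `blockEffects` (scenarios 3-6: per block, `subsets`, `labels`,
#'   `effects`, `cov`).
#' @export
drawEffects <- function(spec, qtl, blocks = NULL, seed = NULL) {
  sa2 <- spec$sigmaA2
  withSeed(seed, {
    if (spec$scenario == 1L) {
      return(list(additive = stats::rnorm(length(qtl$qtl), 0, sqrt(sa2))))
    }
    if (spec$scenario == 2L) {
      saa2 <- sa2 * spec$ratio[2] / spec$ratio[1]
      return(list(
        additive = stats::rnorm(length(qtl$qtl), 0, sqrt(sa2)),
        pairEffects = stats::rnorm(nrow(qtl$pairs), 0, sqrt(saa2))))
    }
    stopifnot(!is.null(blocks))
    digenicOnly <- spec$scenario %in% c(3L, 5L)
    correlated <- spec$scenario %in% c(5L, 6L)
    covCache <- list()
    blockEffects <- lapply(blocks, function(idx) {
      p <- length(idx)
      key <- as.character(p)
      if (is.null(covCache[[key]])) {
        cv <- blockEffectCovariance(p, sigma_h2 = sa2)
        cv <- adjustVarianceRatio(cv, spec$ratio)
        covCache[[key]] <<- cv
      }
      cv <- covCache[[key]]
      if (digenicOnly) cv <- truncateCovariance(cv, 2)
      eff <- if (correlated) {
        drop(crossprod(chol(addJitter(unclass(cv), 1e-10)),
                       stats::rnorm(nrow(cv))))
      } else {
        stats::rnorm(nrow(cv), 0, sqrt(diag(cv)))
      }
      list(markers = idx, subsets = attr(cv, "subsets"),
           labels = attr(cv, "labels"), effects = eff,
           cov = if (correlated) cv else diag(diag(cv)))
    })
    list(blockEffects = blockEffects)
  })
}

#' Genetic values from genotypes, QTL and effects
#'
#' Scenario 1: g = M a over the QTL; scenario 2: g = M a + F aa with F the
#' pairwise-product design of the sampled pairs; scenarios 3-6:
#' g = sum_k Z_k alpha_k with Z_k the subset-product design of block k
#' (truncated at digenic terms for scenarios 3 and 5).
#'
#' @param g a [GenotypeData-class] panel.
#' @param qtl result of [sampleQtl()].
#' @param effects result of [drawEffects()].
#' @param spec a [scenarioSpec()].
#' @return numeric vector of genetic values, one per individual.
#' @export
geneticValues <- function(g, qtl, effects, spec) {
  M <- genoCodes(g)
  if (spec$scenario %in% 1:2) {
    if (length(effects$additive) != length(qtl$qtl))
      stop("additive effect vector does not match QTL count")
    gv <- unname(drop(M[, qtl$qtl, drop = FALSE] %*% effects$additive))
    if (spec$scenario == 2L) {
      if (nrow(qtl$pairs) != length(effects$pairEffects))
        stop("pair effect vector does not match pair count")
      F_ <- M[, qtl$pairs[, 1], drop = FALSE] *
        M[, qtl$pairs[, 2], drop = FALSE]
      gv <- gv + drop(F_ %*% effects$pairEffects)
    }
    return(gv)
  }
  maxOrder <- if (spec$scenario %in% c(3L, 5L)) 2 else Inf
  gv <- numeric(nrow(M))
  for (be in effects$blockEffects) {
    des <- buildEpistaticDesign(M, block = be$markers, maxOrder = maxOrder)
    if (ncol(des$Z) != length(be$effects))
      stop("block effect vector does not match design width")
    gv <- gv + drop(des$Z %*% be$effects)
  }
  gv
}

#' Add environmental noise at a target heritability
#'
#' e ~ N(0, sigma_e^2 I) with sigma_e^2 = ((1 - h2) / h2) var(g), so the
#' expected realized heritability var(g)/var(y) equals `h2`.
#'
#' @param gv genetic values.
#' @param h2 target heritability in (0, 1].
#' @param seed RNG seed.
#' @return phenotype vector y = g + e.
#' @export
simulatePhenotype <- function(gv, h2, seed = NULL) {
  stopifnot(h2 > 0, h2 <= 1)
  vg <- stats::var(gv)
  if (!is.finite(vg) || vg <= 0)
    stop("genetic values are constant: cannot scale the error variance")
  if (h2 == 1) return(gv)
  se2 <- (1 - h2) / h2 * vg
  withSeed(seed, gv + stats::rnorm(length(gv), 0, sqrt(se2)))
}

#' Simulate a complete trait replicate
#'
#' Runs QTL sampling, block partitioning, effect drawing, genetic-value
#' computation and phenotype simulation under one RNG stream, so a
#' (scenario, seed) pair reproduces the replicate exactly.
#'
#' @param g a [GenotypeData-class] panel.
#' @param spec a [scenarioSpec()].
#' @param seed RNG seed.
#' @return object of class `hgblup_trait`: list with `g` (genetic values),
#'   `y` (phenotypes), `qtl`, `blocks`, `effects`, `realizedH2`
#'   (var(g)/var(y)) and `spec`.
#' @export
simulateTrait <- function(g, spec, seed = NULL) {
  withSeed(seed, {
    qtl <- sampleQtl(g, spec)
    blocks <- if (spec$scenario >= 3L)
      partitionQtlBlocks(qtl$qtl, markerMap(g), spec) else NULL
    eff <- drawEffects(spec, qtl, blocks)
    gv <- geneticValues(g, qtl, eff, spec)
    y <- simulatePhenotype(gv, spec$h2)
    names(gv) <- names(y) <- sampleIds(g)
    structure(list(g = gv, y = y, qtl = qtl, blocks = blocks,
                   effects = eff, realizedH2 = stats::var(gv) / stats::var(y),
                   spec = spec),
              class = "hgblup_trait")
  })
}

#' @export
print.hgblup_trait <- function(x, ...) {
  cat("Simulated trait: scenario", x$spec$scenario,
      "| target h2 =", x$spec$h2,
      "| realized h2 =", round(x$realizedH2, 3), "\n")
  cat("  ", length(x$qtl$qtl), "QTL",
      if (!is.null(x$blocks)) paste("in", length(x$blocks), "blocks"), "\n")
  invisible(x)
}
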