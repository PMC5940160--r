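#' Random k-fold assignments
#'
#' Balanced random partition of n individuals into k folds (sizes differing
#' by at most 1), repeated `repeats` times under one seeded stream.
#'
#' @param n number of individuals.
#' @param k number of folds (default 5).
#' @param repeats number of independent fold partitions.
#' @param seed RNG seed.
#' @return integer matrix n x repeats of fold labels in 1..k.
#' @export
makeFolds <- function(n, k = 5, repeats = 1, seed = NULL) {
  stopifnot(n >= k, k >= 2)
  withSeed(seed, {
    f <- vapply(seq_len(repeats), function(r)
      sample(rep_len(seq_len(k), n)), integer(n))
    if (n == 1) f <- matrix(f, nrow = 1)
    f
  })
}

#' Prediction accuracy / ability
#'
#' Sample Pearson correlation between predicted and reference values.  With
#' simulated data the reference is the true genetic value (accuracy); with
#' empirical data it is the observed phenotype (predictive ability).
#'
#' @param predicted,reference numeric vectors of equal length (>= 3 pairs).
#' @return Pearson r, or `NA` (with a warning) when either vector has zero
#'   variance.
#' @export
accuracy <- function(predicted, reference) {
  ok <- stats::complete.cases(predicted, reference)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  p <- predicted[ok]; r <- reference[ok]
  if (stats::sd(p) == 0 || stats::sd(r) == 0) {
    warning("zero variance: accuracy undefined")
    return(NA_real_)
  }
  stats::cor(p, r)
}

#' Kernels for a named prediction model
#'
#' `gblup` uses the additive kernel G1; `egblup` adds the genome-wide
#' digenic kernel; `legblup` adds the within-window digenic kernel instead;
#' `hgblup` uses the haplotype kernel alone.
#'
#' @param g a [GenotypeData-class] panel.
#' @param model one of `"gblup"`, `"egblup"`, `"legblup"`, `"hgblup"`.
#' @param window block length for `legblup` / `hgblup`.
#' @param phased optional [PhasedGenotypes-class] for heterozygous panels.
#' @param seed phase seed for heterozygous panels without `phased`.
#' @return list of [GenomicKernel-class] objects.
#' @export
modelKernels <- function(g, model = c("gblup", "egblup", "legblup", "hgblup"),
                         window = NULL, phased = NULL, seed = NULL) {
  model <- match.arg(model)
  if (model %in% c("legblup", "hgblup")) {
    if (is.null(window)) stop(model, " requires a window length")
    if (model == "legblup" && window < 2)
      stop("local-epistasis kernels need window >= 2")
  }
  switch(model,
    gblup = list(additive = additiveKernel(g)),
    egblup = list(additive = additiveKernel(g),
                  epistatic = globalDigenicKernel(g)),
    legblup = {
      part <- partitionFixedWindows(markerMap(g), window)
      list(additive = additiveKernel(g),
           epistatic = localDigenicKernel(g, part))
    },
    hgblup = list(haplotype =
      haplotypeKernelFromGenotypes(g, window, phased = phased, seed = seed))
  )
}

#' Cross-validated comparison of prediction models
#'
#' Runs repeated k-fold cross-validation for each requested (model, window)
#' combination.  Kernels are computed once on the full panel per combination
#' and reused across folds and repeats; fold assignments are shared across
#' models within a repeat, giving a paired comparison.
#'
#' @param g a [GenotypeData-class] panel.
#' @param y named phenotype vector over the panel.
#' @param reference values to correlate predictions with on the held-out
#'   fold: true genetic values for simulated data (accuracy); defaults to
#'   `y` (predictive ability).
#' @param models character subset of `c("gblup", "egblup", "legblup",
#'   "hgblup")`.
#' @param windows integer window lengths for the block-based models.
#' @param k folds (default 5).
#' @param repeats CV repeats (default 20).
#' @param seed RNG seed for the folds.
#' @param ... further arguments to [fitKernelModel()].
#' @return data.frame (long format) with columns model, window, repeat_,
#'   fold, r; a summary data.frame (mean and standard error of r per model x
#'   window, SE = sd over the fold-level estimates / sqrt(#estimates)) is
#'   attached as `attr(x, "summary")`.
#' @export
runComparison <- function(g, y, reference = y,
                          models = c("gblup", "hgblup"),
                          windows = 2:5, k = 5, repeats = 20, seed = NULL,
                          ...) {
  stopifnot(length(y) == nSamples(g))
  if (is.null(names(y))) names(y) <- sampleIds(g)
  folds <- makeFolds(length(y), k = k, repeats = repeats, seed = seed)
  grid <- do.call(rbind, lapply(models, function(m)
    if (m %in% c("legblup", "hgblup"))
      data.frame(model = m, window = windows)
    else data.frame(model = m, window = NA_integer_)))
  rows <- vector("list", 0)
  for (i in seq_len(nrow(grid))) {
    ks <- modelKernels(g, grid$model[i],
                       window = if (is.na(grid$window[i])) NULL
                                else grid$window[i])
    for (r in seq_len(repeats)) for (f in seq_len(k)) {
      test <- folds[, r] == f
      ytr <- y
      ytr[test] <- NA
      fit <- fitKernelModel(ytr, ks, ...)
      pred <- fit$totalGHat[test]
      rows[[length(rows) + 1]] <- data.frame(
        model = grid$model[i], window = grid$window[i], repeat_ = r,
        fold = f, r = accuracy(pred, reference[test]))
    }
  }
  out <- do.call(rbind, rows)
  tmp <- out
  tmp$window[is.na(tmp$window)] <- -1L   # keep window-free models in aggregate
  agg <- stats::aggregate(r ~ model + window, tmp,
                          function(v) c(mean = mean(v),
                                        se = stats::sd(v) / sqrt(length(v))))
  summ <- data.frame(model = agg$model,
                     window = ifelse(agg$window < 0, NA_integer_, agg$window),
                     mean = agg$r[, "mean"], se = agg$r[, "se"])
  attr(out, "summary") <- summ
  attr(out, "folds") <- folds
  out
}
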