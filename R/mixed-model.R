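#' Fit a multi-kernel variance-component mixed model
#'
#' Fits y = 1 mu + g_1 + ... + g_T + e with g_t ~ N(0, sigma_t^2 K_t) and
#' e ~ N(0, sigma_e^2 I), the common form of GBLUP (one additive kernel),
#' HGBLUP (one haplotype kernel), EGBLUP and LEGBLUP (additive + digenic
#' epistatic kernels).  Samples with `NA` phenotype are excluded from the
#' likelihood but receive BLUP predictions through the train x test kernel
#' blocks (kernels are built once on the whole panel, the usual transductive
#' genomic-prediction setup).
#'
#' REML estimation uses an eigendecomposition profile likelihood for a
#' single kernel and average-information (AI) updates with a safeguarded
#' multiplicative fallback for several kernels; iteration stops when the
#' relative change in the restricted log-likelihood falls below `tol`.
#' The Gibbs sampler re-expresses each kernel through its eigenvectors as a
#' ridge regression and places scaled-inverse-chi-square priors (default 5
#' degrees of freedom, prior mode = half the phenotypic variance split
#' equally across components) on the variance components; posterior means
#' are reported and predictions use the posterior-mean components.
#'
#' @param y named numeric vector over the panel; `NA` marks individuals to
#'   predict.
#' @param kernels a [GenomicKernel-class], a plain symmetric matrix, or a
#'   list of these (all n x n over the same samples, in `names(y)` order).
#' @param method `"reml"` (default, deterministic) or `"gibbs"`.
#' @param varComp optional fixed variance components, `c(sigma_1^2, ...,
#'   sigma_T^2, sigma_e^2)`; skips estimation (useful for testing model
#'   equivalences at matched components).
#' @param maxit,tol REML iteration cap and relative log-likelihood
#'   convergence tolerance.
#' @param burnin,iter Gibbs burn-in and kept iterations.
#' @param priorDf prior degrees of freedom for the Gibbs variance priors.
#' @param seed RNG seed for the Gibbs path.
#' @return object of class `hgblup_fit`: list with `mu`, `varComp` (named,
#'   error variance last), `gHat` (n x T matrix of per-kernel BLUPs over the
#'   whole panel), `totalGHat`, `fitted`, `logLik`, `iterations`,
#'   `converged`, `method`, `observed` (ids used in the likelihood).
#' @export
fitKernelModel <- function(y, kernels, method = c("reml", "gibbs"),
                           varComp = NULL, maxit = 500, tol = 1e-8,
                           burnin = 500, iter = 1500, priorDf = 5,
                           seed = NULL) {
  method <- match.arg(method)
  Ks <- normalizeKernels(kernels, y)
  n <- length(y)
  obs <- which(!is.na(y))
  if (length(obs) < 2) stop("need at least two observed phenotypes")
  yo <- as.numeric(y[obs])
  Ko <- lapply(Ks, function(K) addJitter(K[obs, obs, drop = FALSE]))
  T_ <- length(Ks)
  for (K in Ko)
    if (inherits(tryCatch(chol(K), error = function(e) e), "error"))
      stop("kernel is not positive semi-definite after regularization")
  vy <- stats::var(yo)

  if (!is.null(varComp)) {
    stopifnot(length(varComp) == T_ + 1, all(varComp >= 0))
    est <- list(varComp = varComp, iterations = 0L, converged = TRUE,
                logLik = remlLogLik(yo, Ko, varComp))
  } else if (method == "gibbs") {
    est <- gibbsVarComp(yo, Ko, burnin = burnin, iter = iter,
                        priorDf = priorDf, seed = seed)
  } else if (T_ == 1) {
    est <- remlSingleKernel(yo, Ko[[1]])
  } else {
    est <- remlMultiKernel(yo, Ko, maxit = maxit, tol = tol)
  }
  vc <- est$varComp
  # report components that collapsed to the boundary as 0
  tiny <- vc < 1e-6 * sum(vc)
  vcReport <- ifelse(tiny, 0, vc)

  # BLUPs at the estimated components, over the whole panel
  Vo <- Reduce(`+`, Map(function(K, s) s * K, Ko, vc[seq_len(T_)])) +
    diag(vc[T_ + 1] + 1e-10 * vy, length(obs))
  Vi <- chol2inv(chol(Vo))
  vi1 <- rowSums(Vi)
  mu <- sum(vi1 * yo) / sum(vi1)
  Py <- Vi %*% (yo - mu)
  gHat <- vapply(seq_len(T_), function(t)
    as.numeric(vc[t] * (Ks[[t]][, obs, drop = FALSE] %*% Py)), numeric(n))
  if (n == 1) gHat <- matrix(gHat, nrow = 1)
  knames <- names(Ks)
  dimnames(gHat) <- list(names(y), knames)
  total <- rowSums(gHat)
  names(vcReport) <- c(knames, "error")
  structure(list(
    mu = mu, varComp = vcReport, gHat = gHat, totalGHat = total,
    fitted = mu + total, logLik = est$logLik,
    iterations = est$iterations, converged = est$converged,
    method = if (!is.null(varComp)) "fixed" else method,
    observed = names(y)[obs],
    posterior = est$posterior
  ), class = "hgblup_fit")
}

normalizeKernels <- function(kernels, y) {
  if (is(kernels, "GenomicKernel") || is.matrix(kernels))
    kernels <- list(kernels)
  Ks <- lapply(kernels, function(k) {
    K <- if (is(k, "GenomicKernel")) kernelValues(k) else as.matrix(k)
    if (nrow(K) != length(y))
      stop("kernel dimension ", nrow(K), " does not match phenotype length ",
           length(y))
    if (!is.null(names(y)) && !is.null(rownames(K)) &&
        !identical(rownames(K), names(y)))
      stop("kernel sample ids do not match phenotype names")
    K
  })
  nm <- names(Ks)
  kind <- vapply(kernels, function(k)
    if (is(k, "GenomicKernel")) kernelKind(k) else "kernel", character(1))
  if (is.null(nm)) nm <- rep("", length(Ks))
  nm[nm == ""] <- make.unique(kind[nm == ""], sep = "")
  names(Ks) <- nm
  Ks
}

remlLogLik <- function(yo, Ko, vc) {
  n <- length(yo)
  V <- Reduce(`+`, Map(function(K, s) s * K, Ko, vc[-length(vc)])) +
    diag(vc[length(vc)], n)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Vi <- chol2inv(ch)
  vi1 <- rowSums(Vi)
  xvx <- sum(vi1)
  mu <- sum(vi1 * yo) / xvx
  r <- yo - mu
  -0.5 * (2 * sum(log(diag(ch))) + log(xvx) + sum(r * (Vi %*% r)))
}

# Single-kernel REML via eigendecomposition and a 1-d profile likelihood in
# the variance ratio delta = sigma_e^2 / sigma_g^2 (EMMA-style).
remlSingleKernel <- function(yo, K) {
  n <- length(yo)
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  ty <- crossprod(eg$vectors, yo)[, 1]
  tx <- crossprod(eg$vectors, rep(1, n))[, 1]
  prof <- function(ld) {
    w <- d + exp(ld)
    xx <- sum(tx^2 / w)
    mu <- sum(tx * ty / w) / xx
    r2 <- sum((ty - tx * mu)^2 / w)
    sg2 <- r2 / (n - 1)
    # negative restricted log-likelihood up to a constant
    0.5 * ((n - 1) * log(sg2) + sum(log(w)) + log(xx))
  }
  opt <- stats::optimize(prof, interval = log(c(1e-9, 1e9)), tol = 1e-12)
  delta <- exp(opt$minimum)
  w <- d + delta
  xx <- sum(tx^2 / w)
  mu <- sum(tx * ty / w) / xx
  sg2 <- sum((ty - tx * mu)^2 / w) / (n - 1)
  vc <- c(sg2, delta * sg2)
  list(varComp = vc, iterations = 1L, converged = TRUE,
       logLik = remlLogLik(yo, list(K), vc), posterior = NULL)
}

# Multi-kernel AI-REML with a multiplicative safeguarded fallback whenever a
# Newton step would leave the parameter space or decrease the likelihood.
remlMultiKernel <- function(yo, Ko, maxit = 500, tol = 1e-8) {
  n <- length(yo)
  T_ <- length(Ko)
  vy <- stats::var(yo)
  floor_ <- 1e-10 * vy
  theta <- c(rep(0.5 * vy / T_, T_), 0.5 * vy)
  Kall <- c(Ko, list(diag(1, n)))
  ll <- remlLogLikTheta(yo, Kall, theta)$ll
  converged <- FALSE
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    st <- remlLogLikTheta(yo, Kall, theta)
    P <- st$P; Py <- st$Py
    wvec <- lapply(Kall, function(K) K %*% Py)
    score <- vapply(seq_along(Kall), function(t)
      -0.5 * (sum(P * Kall[[t]]) - sum(Py * wvec[[t]])), numeric(1))
    AI <- matrix(0, T_ + 1, T_ + 1)
    Pw <- lapply(wvec, function(w) P %*% w)
    for (a in seq_len(T_ + 1)) for (b in a:(T_ + 1))
      AI[a, b] <- AI[b, a] <- 0.5 * sum(wvec[[a]] * Pw[[b]])
    step <- tryCatch(solve(AI + diag(1e-8 * max(diag(AI)), T_ + 1), score),
                     error = function(e) NULL)
    cand <- if (is.null(step)) NULL else pmax(theta + step, floor_)
    ok <- !is.null(cand)
    if (ok) {
      llc <- remlLogLikTheta(yo, Kall, cand)$ll
      if (!is.finite(llc) || llc < ll - 1e-10) ok <- FALSE
    }
    if (!ok) {
      # safeguarded multiplicative update; fixed point = REML equations
      ratio <- vapply(seq_along(Kall), function(t) {
        num <- sum(Py * wvec[[t]]); den <- sum(P * Kall[[t]])
        if (den <= 0) 1 else sqrt(max(num, 0) / den)
      }, numeric(1))
      cand <- pmax(theta * pmin(pmax(ratio, 0.1), 10), floor_)
      llc <- remlLogLikTheta(yo, Kall, cand)$ll
    }
    theta <- pmax(cand, floor_)
    if (is.finite(llc) && abs(llc - ll) < tol * (1 + abs(llc))) {
      ll <- llc; converged <- TRUE; break
    }
    ll <- llc
  }
  list(varComp = theta, iterations = it, converged = converged,
       logLik = ll, posterior = NULL)
}

remlLogLikTheta <- function(yo, Kall, theta) {
  n <- length(yo)
  V <- Reduce(`+`, Map(function(K, s) s * K, Kall, theta))
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf, P = NULL, Py = NULL))
  Vi <- chol2inv(ch)
  vi1 <- rowSums(Vi)
  xvx <- sum(vi1)
  P <- Vi - tcrossprod(vi1) / xvx
  Py <- P %*% yo
  ll <- -0.5 * (2 * sum(log(diag(ch))) + log(xvx) + sum(yo * Py))
  list(ll = ll, P = P, Py = Py)
}

# Gibbs sampler on the eigen-basis ridge representation of each kernel.
gibbsVarComp <- function(yo, Ko, burnin, iter, priorDf, seed) {
  n <- length(yo)
  T_ <- length(Ko)
  vy <- stats::var(yo)
  W <- lapply(Ko, function(K) {
    eg <- eigen(K, symmetric = TRUE)
    keep <- eg$values > 1e-10 * max(eg$values)
    eg$vectors[, keep, drop = FALSE] %*%
      diag(sqrt(eg$values[keep]), sum(keep))
  })
  m <- vapply(W, ncol, integer(1))
  nu0 <- priorDf
  # prior mode nu0 s0 / (nu0 + 2) = 0.5 vy / T (genetic) or 0.5 vy (error)
  s0g <- 0.5 * vy / T_ * (nu0 + 2) / nu0
  s0e <- 0.5 * vy * (nu0 + 2) / nu0
  withSeed(seed, {
    b <- lapply(m, function(k) rep(0, k))
    sg2 <- rep(0.5 * vy / T_, T_)
    se2 <- 0.5 * vy
    mu <- mean(yo)
    keepVc <- matrix(0, iter, T_ + 1)
    keepMu <- numeric(iter)
    keepG <- matrix(0, n, T_)
    fitted_t <- lapply(seq_len(T_), function(t) W[[t]] %*% b[[t]])
    for (s in seq_len(burnin + iter)) {
      resid <- yo - Reduce(`+`, fitted_t)
      mu <- stats::rnorm(1, mean(resid), sqrt(se2 / n))
      for (t in seq_len(T_)) {
        others <- if (T_ > 1) Reduce(`+`, fitted_t[-t]) else 0
        rt <- yo - mu - others
        C <- crossprod(W[[t]]) / se2 + diag(1 / sg2[t], m[t])
        ch <- chol(C)
        mn <- backsolve(ch, forwardsolve(t(ch), crossprod(W[[t]], rt) / se2))
        b[[t]] <- as.numeric(mn + backsolve(ch, stats::rnorm(m[t])))
        fitted_t[[t]] <- W[[t]] %*% b[[t]]
        ss <- sum(b[[t]]^2)
        sg2[t] <- (nu0 * s0g + ss) / stats::rchisq(1, nu0 + m[t])
      }
      resid <- yo - mu - Reduce(`+`, fitted_t)
      se2 <- (nu0 * s0e + sum(resid^2)) / stats::rchisq(1, nu0 + n)
      if (s > burnin) {
        keepVc[s - burnin, ] <- c(sg2, se2)
        keepMu[s - burnin] <- mu
        keepG <- keepG + do.call(cbind, fitted_t)
      }
    }
    list(varComp = colMeans(keepVc), iterations = burnin + iter,
         converged = TRUE, logLik = NA_real_,
         posterior = list(varCompDraws = keepVc, mu = mean(keepMu),
                          gObs = keepG / iter))
  })
}

#' @export
print.hgblup_fit <- function(x, ...) {
  cat("Kernel mixed model (", x$method, ")\n", sep = "")
  cat("  mu:", format(x$mu, digits = 4), "\n")
  cat("  variance components:\n")
  print(round(x$varComp, 5))
  cat("  logLik:", format(x$logLik, digits = 6), " converged:",
      x$converged, "\n")
  invisible(x)
}

#' Predicted genetic values for selected individuals
#'
#' Conditional-expectation BLUP: the per-kernel genetic values of every
#' individual in the kernels (observed or not) are obtained from the train x
#' target kernel blocks; this extracts their sum for the requested ids.
#'
#' @param fit result of [fitKernelModel()].
#' @param ids character ids (or integer indices) of the target individuals.
#' @return named numeric vector of total predicted genetic values.
#' @export
predictGenetic <- function(fit, ids) {
  g <- fit$totalGHat
  if (is.character(ids)) {
    miss <- setdiff(ids, names(g))
    if (length(miss))
      stop("ids absent from the fitted kernels: ",
           paste(miss, collapse = ", "))
  }
  g[ids]
}

#' Write a fit summary as JSON
#'
#' Reports the intercept, variance components and the per-kernel share of
#' phenotypic variance sigma_t^2 mean(diag K_t) / total.
#'
#' @param fit result of [fitKernelModel()].
#' @param kernels the kernels the model was fitted with.
#' @param path output file.
#' @export
writeFitSummary <- function(fit, kernels, path) {
  if (!is.list(kernels) || is(kernels, "GenomicKernel"))
    kernels <- list(kernels)
  vc <- fit$varComp
  T_ <- length(vc) - 1
  expl <- vapply(seq_len(T_), function(t)
    vc[t] * mean(diag(kernelAsMatrix(kernels[[t]]))), numeric(1))
  tot <- sum(expl) + vc[T_ + 1]
  jsonlite::write_json(list(
    mu = fit$mu, variance_components = as.list(vc),
    variance_explained = as.list(stats::setNames(expl / tot,
                                                 names(vc)[seq_len(T_)])),
    logLik = fit$logLik, converged = fit$converged, method = fit$method
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

kernelAsMatrix <- function(k) if (is(k, "GenomicKernel")) kernelValues(k) else as.matrix(k)
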