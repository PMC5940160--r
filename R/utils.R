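# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.  seed = NULL uses the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Moore-Penrose pseudoinverse via SVD; tolerance relative to the largest
# singular value (same convention as LAPACK-based implementations).
pinv <- function(A, tol = sqrt(.Machine$double.eps)) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Paste marker alleles (0/1 per chromosome copy) into haplotype strings.
hapStrings <- function(haps) {
  if (ncol(haps) == 1) return(as.character(haps[, 1]))
  do.call(paste0, as.data.frame(haps))
}

# Column-wise product over a set of columns of a matrix.
colProduct <- function(m, idx) {
  out <- m[, idx[1]]
  for (j in idx[-1]) out <- out * m[, j]
  out
}

# All non-empty marker subsets of 1..p, ordered by (size, lexicographic).
# Optionally truncated at subsets of size <= maxOrder.
markerSubsets <- function(p, maxOrder = p) {
  stopifnot(p >= 1)
  if (p > 12) stop("block size ", p, " exceeds the supported limit of 12 ",
                   "(design width 2^p - 1)")
  out <- list()
  for (t in seq_len(min(p, maxOrder)))
    out <- c(out, utils::combn(p, t, simplify = FALSE))
  out
}

subsetLabels <- function(subsets, markerIds = NULL) {
  vapply(subsets, function(s) {
    nm <- if (is.null(markerIds)) paste0("m", s) else markerIds[s]
    paste(nm, collapse = ":")
  }, character(1))
}

addJitter <- function(K, eps = 1e-8) {
  d <- mean(diag(K))
  if (d <= 0) d <- 1
  K + diag(eps * d, nrow(K))
}
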