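#' Build the full local-epistasis design matrix Z for a block
#'
#' Columns of Z are indexed by the non-empty subsets of the block's markers,
#' ordered by (subset size, lexicographic); the column for a subset is the
#' elementwise product of the raw 0/1/2 code columns of its markers.  Size-1
#' subsets give the additive design, size-2 the digenic epistatic design, and
#' so on up to the interaction among all p markers, for a total of 2^p - 1
#' columns.  For fully homozygous data the entry of an order-t column is
#' 2^t when the individual is a homozygous carrier at all t markers of the
#' subset and 0 otherwise.
#'
#' @param g a [GenotypeData-class] object or a raw code matrix.
#' @param block integer vector of marker column indices forming the block
#'   (default: all markers).
#' @param maxOrder truncate the design at subsets of this size (default: all
#'   orders up to p).
#' @return list with elements `Z` (n x (2^p - 1) matrix), `subsets` (list of
#'   marker-index tuples, relative to `block`) and `labels`
#'   (e.g. `"m1"`, `"m1:m2"`).
#' @export
buildEpistaticDesign <- function(g, block = NULL, maxOrder = Inf) {
  M <- if (is(g, "GenotypeData")) genoCodes(g) else as.matrix(g)
  if (is.null(block)) block <- seq_len(ncol(M))
  C <- M[, block, drop = FALSE]
  p <- ncol(C)
  ss <- markerSubsets(p, maxOrder = min(p, maxOrder))
  Z <- vapply(ss, function(s) colProduct(C, s), numeric(nrow(C)))
  if (nrow(C) == 1) Z <- matrix(Z, nrow = 1)
  lab <- subsetLabels(ss)
  colnames(Z) <- lab
  rownames(Z) <- rownames(C)
  list(Z = Z, subsets = ss, labels = lab)
}

#' Representative rows of an inbred block design
#'
#' For each haplotype-allele column of a fully homozygous block design the
#' first individual carrying that allele (with two copies) is selected; the
#' resulting submatrix equals 2 times a permutation of the identity, hence is
#' invertible.
#'
#' @param X block design matrix over haplotype alleles (entries 0/2).
#' @return integer vector of row indices, one per column of `X`.
#' @export
selectRepresentativeRows <- function(X) {
  if (any(X == 1))
    stop("heterozygous row encountered: representative-row selection is ",
         "defined for fully homozygous data")
  idx <- vapply(seq_len(ncol(X)), function(j) {
    i <- which(X[, j] == 2)
    if (!length(i)) stop("allele column ", j, " has no carrier")
    i[1]
  }, integer(1))
  idx
}

#' Linear transformation from haplotype effects to marker/epistatic effects
#'
#' For a fully homozygous block, computes the (2^p - 1) x s matrix V with
#' X = Z V, where X is the haplotype-allele design (after dropping the
#' redundant all-zero-code allele) and Z the full local-epistasis design.
#' When every nonzero-code haplotype is observed (s = 2^p - 1) the
#' representative-row submatrix Ztilde is invertible and V = Ztilde^-1
#' Xtilde; otherwise Ztilde has full row rank and V = W Xtilde with W the
#' Moore-Penrose right inverse of Ztilde.  The induced covariance of the
#' transformed effects beta = V h is V V' sigma_h^2, which is the
#' non-diagonal effect covariance the haplotype model implicitly assumes.
#'
#' @param g a [GenotypeData-class] object (fully homozygous on `block`).
#' @param block integer vector of marker column indices (default: all).
#' @param tol absolute tolerance declaring X = Z V exact (designs are
#'   integer-valued, so 1e-10 is conservative).
#' @return object of class `hgblup_transform`: list with `V`, `cov`
#'   (= V V'), `Xtilde`, `Ztilde`, `alleles`, `labels`, `representatives`,
#'   `case` ("all_alleles" or "right_inverse"), `maxResidual`, `exact`.
#' @examples
#' g <- GenotypeData(matrix(c(2,2, 2,0, 0,2, 0,0, 2,0, 2,2), ncol = 2,
#'                          byrow = TRUE),
#'                   data.frame(marker_id = c("m1","m2"), chrom = "1",
#'                              pos = 1:2))
#' tr <- computeTransform(g)
#' tr$V        # haplotype -> marker/epistatic effect map
#' tr$cov      # implied effect covariance (additive + digenic)
#' @export
computeTransform <- function(g, block = NULL, tol = 1e-10) {
  M <- genoCodes(g)
  if (is.null(block)) block <- seq_len(ncol(M))
  C <- M[, block, drop = FALSE]
  if (any(C == 1))
    stop("heterozygous data: no linear transformation X = Z V exists in ",
         "general (see checkHeterozygousObstruction)")
  p <- ncol(C)
  hap <- hapStrings(C / 2)
  zero <- strrep("0", p)
  retained <- sort(setdiff(unique(hap), zero), decreasing = TRUE)
  s <- length(retained)
  if (s == 0) stop("block is monomorphic for the all-zero haplotype")
  X <- 2 * outer(hap, retained, "==")
  dimnames(X) <- list(rownames(C), retained)
  rep_ <- vapply(retained, function(a) which(hap == a)[1], integer(1))
  des <- buildEpistaticDesign(C)
  Ztilde <- des$Z[rep_, , drop = FALSE]
  Xtilde <- X[rep_, , drop = FALSE]
  full <- s == 2^p - 1
  V <- if (full) solve(Ztilde, Xtilde) else pinv(Ztilde) %*% Xtilde
  dimnames(V) <- list(des$labels, retained)
  resid <- max(abs(X - des$Z %*% V))
  structure(list(
    V = V, cov = tcrossprod(V),
    Xtilde = Xtilde, Ztilde = Ztilde,
    alleles = retained, labels = des$labels, subsets = des$subsets,
    representatives = unname(rep_),
    case = if (full) "all_alleles" else "right_inverse",
    maxResidual = resid, exact = resid <= tol
  ), class = "hgblup_transform")
}

#' @export
print.hgblup_transform <- function(x, ...) {
  cat("Haplotype -> local-epistasis transform (", x$case, ")\n", sep = "")
  cat("  alleles:", paste(x$alleles, collapse = ", "), "\n")
  cat("  exact (max |X - ZV| = ", format(x$maxResidual), "): ", x$exact,
      "\n", sep = "")
  invisible(x)
}

#' Demonstrate the heterozygous obstruction to the transform
#'
#' When heterozygous loci are present, rows of the haplotype design X can
#' carry two entries equal to 1 and no matrix V with X = Z V exists in
#' general.  This function determines the unique candidate V from the fully
#' homozygous individuals (where the transform is well defined) and reports
#' the rows of Z V that fail to reproduce X -- the individuals heterozygous
#' at two or more of the block's loci.
#'
#' @param x a [PhasedGenotypes-class] object (phase is needed to form X for
#'   heterozygotes), or a fully homozygous [GenotypeData-class].
#' @param block integer vector of marker column indices (default: all).
#' @param tol residual threshold for flagging a row.
#' @return list with `V`, `alleles`, `residualByRow`, `offendingRows`
#'   (sample indices where Z V != X) and `maxResidual`.
#' @export
checkHeterozygousObstruction <- function(x, block = NULL, tol = 1e-8) {
  if (is(x, "GenotypeData")) {
    if (!isFullyHomozygous(x))
      stop("supply PhasedGenotypes for heterozygous panels")
    x <- assignRandomPhase(x)   # deterministic: no heterozygotes
  }
  m1 <- maternalHaplotypes(x); m2 <- paternalHaplotypes(x)
  if (is.null(block)) block <- seq_len(ncol(m1))
  m1 <- m1[, block, drop = FALSE]; m2 <- m2[, block, drop = FALSE]
  p <- ncol(m1)
  codes <- m1 + m2
  h1 <- hapStrings(m1); h2 <- hapStrings(m2)
  zero <- strrep("0", p)
  hom <- h1 == h2
  if (!any(hom)) stop("no fully homozygous individuals to anchor the ",
                      "candidate transform")
  anchor <- sort(setdiff(unique(h1[hom]), zero), decreasing = TRUE)
  s <- length(anchor)
  if (s == 0) stop("homozygous individuals are monomorphic all-zero")
  rep_ <- vapply(anchor, function(a) which(hom & h1 == a)[1], integer(1))
  des <- buildEpistaticDesign(codes)
  Ztilde <- des$Z[rep_, , drop = FALSE]
  Xtilde <- diag(2, s)
  V <- if (s == 2^p - 1) solve(Ztilde, Xtilde) else pinv(Ztilde) %*% Xtilde
  dimnames(V) <- list(des$labels, anchor)
  X <- outer(h1, anchor, "==") + outer(h2, anchor, "==")
  resid <- abs(X - des$Z %*% V)
  byRow <- apply(resid, 1, max)
  undet <- setdiff(unique(c(h1, h2)), c(anchor, zero))
  list(V = V, alleles = anchor,
       undeterminedAlleles = undet,
       residualByRow = unname(byRow),
       offendingRows = unname(which(byRow > tol)),
       maxResidual = max(byRow))
}

#' Canonical per-block effect covariance implied by the haplotype model
#'
#' Enumerates all 2^p fully homozygous genotypes of a p-marker block,
#' computes the transform V for that canonical design (every nonzero-code
#' haplotype occurs, so V = Ztilde^-1 Xtilde exactly), and returns the
#' implied covariance V V' sigma_h^2 of the additive and epistatic effects,
#' indexed by marker subsets.  Because the canonical design is
#' sample-independent this is the covariance used by the trait simulator for
#' correlated-effect architectures.  The additive block of the covariance is
#' the identity and the order-t epistatic variances follow the profile
#' 4^(1-t) (2^t - 1) sigma_h^2, giving the additive : digenic variance ratio
#' 4:3 for every block size.
#'
#' @param p block size in markers (p <= 12).
#' @param sigma_h2 haplotype-effect variance multiplying V V'.
#' @return covariance matrix over the 2^p - 1 marker subsets, with
#'   attributes `subsets`, `labels` and `order` (subset sizes).
#' @export
blockEffectCovariance <- function(p, sigma_h2 = 1) {
  ss <- markerSubsets(p)
  s <- length(ss)
  C <- matrix(0, s, p)
  for (i in seq_len(s)) C[i, ss[[i]]] <- 2
  des <- buildEpistaticDesign(C)
  V <- 2 * solve(des$Z)
  cov <- tcrossprod(V) * sigma_h2
  dimnames(cov) <- list(des$labels, des$labels)
  structure(cov, subsets = ss, labels = des$labels,
            order = lengths(ss))
}

#' Rescale a block effect covariance to a target additive : digenic ratio
#'
#' All epistatic variances (order >= 2) are multiplied by a common factor so
#' that sigma_a^2 / sigma_aa^2 matches `target`, while additive variances,
#' all correlations, and the ratio of any two epistatic variance terms are
#' preserved (covariances are rescaled consistently with the preserved
#' correlations).  The canonical covariance has ratio 4:3, so `target =
#' c(4, 3)` is the identity transformation.
#'
#' @param cov covariance from [blockEffectCovariance()] (must carry the
#'   `order` attribute).
#' @param target numeric pair `c(ra, re)` with sigma_a^2 : sigma_aa^2 =
#'   ra : re.
#' @return rescaled covariance with the same attributes.
#' @export
adjustVarianceRatio <- function(cov, target) {
  stopifnot(length(target) == 2, all(target > 0))
  ord <- attr(cov, "order")
  if (is.null(ord)) stop("cov must come from blockEffectCovariance()")
  d <- diag(cov)
  sa2 <- mean(d[ord == 1])
  if (!any(ord >= 2)) return(cov)   # purely additive block
  saa2 <- mean(d[ord == 2])
  fac <- (target[2] / target[1] * sa2) / saa2
  scl <- ifelse(ord == 1, 1, sqrt(fac))
  out <- cov * outer(scl, scl)
  ev <- eigen(out, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    warning("rescaled covariance not PSD; eigenvalue-clipping applied")
    eg <- eigen(out, symmetric = TRUE)
    out2 <- eg$vectors %*% (pmax(eg$values, 0) * t(eg$vectors))
    dimnames(out2) <- dimnames(out)
    mostattributes(out2) <- attributes(out)
    out <- out2
  }
  attributes(out) <- attributes(cov)
  out
}

# Restrict an effect covariance to additive + digenic terms (orders <= 2).
#' @rdname adjustVarianceRatio
#' @param maxOrder keep subsets up to this size.
#' @export
truncateCovariance <- function(cov, maxOrder = 2) {
  ord <- attr(cov, "order")
  keep <- which(ord <= maxOrder)
  out <- cov[keep, keep, drop = FALSE]
  structure(out, subsets = attr(cov, "subsets")[keep],
            labels = attr(cov, "labels")[keep], order = ord[keep])
}

#' Dump a transform result as JSON
#'
#' @param tr result of [computeTransform()].
#' @param path output file.
#' @export
writeTransformReport <- function(tr, path) {
  jsonlite::write_json(list(
    case = tr$case, alleles = tr$alleles, subset_labels = tr$labels,
    V = tr$V, cov = tr$cov, representatives = tr$representatives,
    max_residual = tr$maxResidual, exact = tr$exact
  ), path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
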