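## Shared rank-correlation machinery.
##
## All three mapping levels are mass-univariate Spearman analyses; the hot
## paths (per-voxel, per-fiber, per-permutation) are expressed as one matrix
## product on centred rank matrices so that cross-validation and permutation
## loops stay cheap.

#' Spearman rank correlation of each matrix column with a vector
#'
#' Computes `cor(X[, j], y, method = "spearman")` for every column at once.
#' Ties receive average ranks, matching [stats::cor()]. Columns with zero
#' rank variance yield `NA`.
#'
#' @param X numeric matrix (n observations x m features).
#' @param y numeric vector of length `nrow(X)`.
#' @param xr optional precomputed result of [rank_cols()] on `X`; pass it when
#'   calling repeatedly with different `y` (permutations, refits).
#' @return numeric vector of length `ncol(X)`.
#' @export
spearman_cols <- function(X, y, xr = NULL) {
  stopifnot(is.matrix(X), length(y) == nrow(X))
  if (nrow(X) < 2L) stop("need at least 2 observations")
  if (is.null(xr)) xr <- rank_cols(X)
  yr <- rank(y)
  yc <- yr - mean(yr)
  ys <- sqrt(sum(yc^2))
  num <- as.vector(crossprod(xr$centered, yc))
  denom <- xr$norms * ys
  out <- num / denom
  out[xr$norms == 0 | ys == 0] <- NA_real_
  out
}

#' Centred column ranks with norms
#'
#' @param X numeric matrix.
#' @return list with `centered` (matrix of centred average ranks) and `norms`
#'   (per-column Euclidean norm; 0 flags a constant column).
#' @export
rank_cols <- function(X) {
  R <- apply(X, 2L, rank)
  if (!is.matrix(R)) R <- matrix(R, nrow = nrow(X))
  R <- sweep(R, 2L, colMeans(R))
  list(centered = R, norms = sqrt(colSums(R^2)))
}

#' Spearman rank correlation of each matrix row with a vector
#'
#' Row-wise counterpart of [spearman_cols()]: `cor(X[i, ], v, "spearman")`
#' for every row. Used to score many patients' weight profiles against one
#' per-fiber R vector.
#'
#' @param X numeric matrix (n rows to score x m features).
#' @param v numeric vector of length `ncol(X)`.
#' @param xr optional precomputed `rank_cols(t(X))`.
#' @return numeric vector of length `nrow(X)`.
#' @export
spearman_rows <- function(X, v, xr = NULL) {
  stopifnot(is.matrix(X), length(v) == ncol(X))
  if (is.null(xr)) xr <- rank_cols(t(X))
  spearman_cols(t(X), v, xr = xr)
}

#' Spearman correlation with a two-sided t-approximation p-value
#'
#' The t approximation `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees
#' of freedom is used throughout the package (mass-univariate settings make
#' exact permutation p-values impractical and tied ranks are common).
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `estimate` (rho), `p.value`, `n`.
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  rho <- suppressWarnings(stats::cor(x, y, method = "spearman"))
  p <- spearman_pvalue(rho, n)
  list(estimate = rho, p.value = p, n = n)
}

## Vectorised two-sided p for a rho vector at common n.
spearman_pvalue <- function(rho, n) {
  p <- rep(NA_real_, length(rho))
  ok <- is.finite(rho)
  r <- pmin(pmax(rho[ok], -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p
}

#' Fisher z-transform with clipping
#'
#' Correlations are clipped to +/- (1 - 1e-7) so that self-correlations map to
#' a large finite value instead of infinity.
#'
#' @param r numeric vector of correlations.
#' @return atanh of the clipped correlations.
#' @export
fisher_z <- function(r) {
  lim <- 1 - 1e-7
  atanh(pmin(pmax(r, -lim), lim))
}
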