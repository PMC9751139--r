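## DBS fiber filtering.
##
## Each streamline is weighted, per patient, by the peak E-field magnitude it
## encounters (nearest-voxel lookup after resampling the polyline finely
## enough that thin voxels cannot be stepped over). Fibers reached with at
## least `e_thr` V/mm by at least a `coverage_fraction` of the cohort's
## stimulation volumes are retained; each retained fiber is assigned the
## Spearman correlation between its weights and clinical improvement across
## the cohort. These mass-univariate R values are descriptive, not
## significance-tested; the model is validated by score-based out-of-sample
## estimation instead.

#' Resample a polyline to a maximum step length
#'
#' Linear interpolation along arc length; endpoints preserved. Used before
#' voxel lookup with `step <= 0.5 * min(voxel size)` so a streamline cannot
#' skip a voxel.
#'
#' @param points n x 3 matrix.
#' @param step maximum distance between consecutive output points (mm).
#' @return m x 3 matrix, m >= n.
#' @export
resample_polyline <- function(points, step) {
  stopifnot(step > 0)
  points <- rbind_mat(points)
  seg <- sqrt(rowSums((points[-1L, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) return(points[1L, , drop = FALSE][c(1L, 1L), , drop = FALSE])
  m <- max(2L, ceiling(total / step) + 1L)
  at <- seq(0, total, length.out = m)
  cbind(stats::approx(s, points[, 1L], xout = at, ties = "ordered")$y,
        stats::approx(s, points[, 2L], xout = at, ties = "ordered")$y,
        stats::approx(s, points[, 3L], xout = at, ties = "ordered")$y)
}

## Resampled points of all fibers, concatenated, with a fiber id per point.
## The resampling step adapts to the grid the weights will be looked up on.
flatten_tractogram <- function(tract, step) {
  pts <- lapply(tract$streamlines, resample_polyline, step = step)
  npts <- vapply(pts, nrow, integer(1L))
  list(points = do.call(rbind, pts),
       fiber = rep.int(seq_along(pts), npts))
}

default_step <- function(grid) {
  0.5 * min(sqrt(colSums(grid$affine[1:3, 1:3]^2)))
}

#' Peak E-field magnitude along each streamline
#'
#' @param E an [efield_image()].
#' @param tract a [tractogram()].
#' @param agg `"peak"` (default) or `"mean"` aggregation along the fiber.
#' @return numeric weight per streamline; fibers entirely outside the grid
#'   get 0.
#' @export
peak_weights <- function(E, tract, agg = c("peak", "mean")) {
  agg <- match.arg(agg)
  if (n_fibers(tract) == 0L) stop("empty tractogram")
  fl <- flatten_tractogram(tract, default_step(E$grid))
  weights_at_points(E, fl, n_fibers(tract), agg)
}

weights_at_points <- function(E, fl, nf, agg) {
  wv <- world_to_voxel(E$grid, fl$points)
  vals <- numeric(nrow(fl$points))
  if (any(wv$inside)) {
    lin <- voxel_linear_index(E$grid, wv$ijk[wv$inside, , drop = FALSE])
    vals[wv$inside] <- E$grid$values[lin]
  }
  out <- numeric(nf)
  agg_fun <- if (agg == "peak") max else mean
  got <- tapply(vals, fl$fiber, agg_fun)
  out[as.integer(names(got))] <- as.numeric(got)
  out
}

#' Fiber weight matrix for a cohort of E-fields
#'
#' @param fields list of [efield_image()].
#' @param tract a [tractogram()].
#' @param agg aggregation along fibers, see [peak_weights()].
#' @return patients x fibers numeric matrix (rows named by patient id).
#' @export
fiber_weight_matrix <- function(fields, tract, agg = c("peak", "mean")) {
  agg <- match.arg(agg)
  if (n_fibers(tract) == 0L) stop("empty tractogram")
  g0 <- fields[[1L]]$grid
  fl <- flatten_tractogram(tract, default_step(g0))
  W <- matrix(0, length(fields), n_fibers(tract))
  for (i in seq_along(fields))
    W[i, ] <- weights_at_points(fields[[i]], fl, n_fibers(tract), agg)
  rownames(W) <- vapply(fields, function(E) E$patient_id, character(1L))
  W
}

#' Coverage-based fiber inclusion
#'
#' A fiber is retained iff it is reached with magnitude >= `e_thr` by at
#' least `coverage_fraction` of the rows (stimulation volumes).
#'
#' @param W patients x fibers weight matrix.
#' @param e_thr magnitude threshold in V/mm (default 0.36).
#' @param coverage_fraction required fraction of rows (default 0.20).
#' @return logical inclusion flag per fiber.
#' @export
filter_fibers <- function(W, e_thr = 0.36, coverage_fraction = 0.20) {
  stopifnot(is.matrix(W), nrow(W) >= 1L)
  colMeans(W >= e_thr) >= coverage_fraction
}

#' Fit the fiber-filtering score model
#'
#' @param W patients x fibers weight matrix.
#' @param outcomes percentage improvement per row of `W`.
#' @param e_thr,coverage_fraction inclusion rule, see [filter_fibers()].
#' @return object of class `fiber_model`: per-fiber `R` (NA where excluded
#'   or degenerate), logical `included`, and the parameters.
#' @export
fit_fiber_model <- function(W, outcomes, e_thr = 0.36, coverage_fraction = 0.20) {
  stopifnot(is.matrix(W))
  if (nrow(W) != length(outcomes)) stop("rows of W must align with outcomes")
  if (nrow(W) < 3L) stop("need at least 3 patients")
  if (stats::sd(outcomes) == 0) stop("zero outcome variance")
  included <- filter_fibers(W, e_thr, coverage_fraction)
  R <- rep(NA_real_, ncol(W))
  if (any(included)) {
    R[included] <- spearman_cols(W[, included, drop = FALSE], outcomes)
    included <- included & !is.na(R)  # drop zero-weight-variance fibers
  }
  if (!any(included)) stop("all fibers excluded")
  structure(list(R = R, included = included,
                 e_thr = e_thr, coverage_fraction = coverage_fraction),
            class = "fiber_model")
}

#' @export
print.fiber_model <- function(x, ...) {
  cat("fiber_model: ", sum(x$included), "/", length(x$included),
      " fibers included (e_thr = ", x$e_thr, " V/mm, coverage >= ",
      x$coverage_fraction * 100, "%)\n", sep = "")
  invisible(x)
}

#' Score an E-field (its fiber weights) against a fitted fiber model
#'
#' The rank-correlation profile of the field's peak weights against the
#' model's per-fiber R values over the model's included fibers: fields that
#' preferentially reach high-R fibers score high. A `positive_only` variant
#' restricts the profile to fibers with positive model R.
#'
#' @param model a [fit_fiber_model()] result.
#' @param weights weight vector aligned to the full fiber set (e.g. one row
#'   of the weight matrix, or [peak_weights()] of a held-out field).
#' @param positive_only restrict to fibers with model R > 0.
#' @return scalar fiber score.
#' @export
score_efield <- function(model, weights, positive_only = FALSE) {
  stopifnot(inherits(model, "fiber_model"))
  if (length(weights) != length(model$R))
    stop("weights must align with the model's fiber set")
  sel <- model$included
  if (positive_only) sel <- sel & model$R > 0
  if (sum(sel) < 3L) stop("too few included fibers to score")
  w <- weights[sel]
  if (stats::sd(w) == 0) stop("zero weight variance under this field")
  suppressWarnings(stats::cor(w, model$R[sel], method = "spearman"))
}

#' Included fibers intersecting a stimulation volume
#'
#' For reporting/export: the model's included fibers whose peak weight under
#' `E` exceeds `e_thr`.
#'
#' @param model a [fit_fiber_model()] result.
#' @param tract the [tractogram()] the model was fitted on.
#' @param E an [efield_image()].
#' @param e_thr magnitude threshold in V/mm; 0 keeps any grid overlap.
#' @return a [tractogram()] subset carrying model R as per-fiber scalar.
#' @export
connected_fibers <- function(model, tract, E, e_thr = model$e_thr) {
  stopifnot(inherits(model, "fiber_model"))
  w <- peak_weights(E, tract)
  idx <- which(model$included & w > e_thr)
  tractogram(tract$streamlines[idx],
             bundle = if (!is.null(tract$bundle)) tract$bundle[idx],
             scalar = model$R[idx])
}
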