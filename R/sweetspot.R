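## Voxel-wise sweetspot / sourspot mapping.
##
## Within a cohort coverage mask, each voxel's E-field magnitudes across
## patients are Spearman-correlated with clinical improvement: positive R
## marks sweet spots (stronger fields there go with better outcomes),
## negative R sour spots. Voxels outside the mask are NaN, never zero, so the
## score-based estimator cannot silently dilute its mean. A mirrored variant
## adds the x-flip of every field with the same outcome, doubling the rows
## and enforcing hemispheric symmetry.

#' Fit a sweetspot map
#'
#' @param fields list of [efield_image()] on one grid.
#' @param outcomes percentage improvement aligned with `fields`.
#' @param thr coverage-mask magnitude threshold in V/mm (default 0.2,
#'   i.e. 200 V/m).
#' @param fraction coverage-mask cohort fraction (default 0.20).
#' @param mirrored also enter each field's mid-sagittal flip with the same
#'   outcome.
#' @return object of class `sweetspot_map`: `rmap` ([voxel_grid()], NaN off
#'   mask), `mask` (logical array), and the parameters.
#' @export
fit_sweetspot <- function(fields, outcomes, thr = 0.2, fraction = 0.2,
                          mirrored = FALSE) {
  if (length(fields) < 3L) stop("need at least 3 fields")
  if (length(fields) != length(outcomes)) stop("fields/outcomes length mismatch")
  if (stats::sd(outcomes) == 0) stop("zero outcome variance")
  if (mirrored) {
    fields <- c(fields, lapply(fields, mirror_efield))
    outcomes <- c(outcomes, outcomes)
  }
  cm <- coverage_mask(fields, thr = thr, fraction = fraction)
  if (!any(cm$mask)) stop("empty coverage mask")
  g0 <- fields[[1L]]$grid
  midx <- which(cm$mask)
  V <- vapply(fields, function(E) E$grid$values[midx],
              numeric(length(midx)))
  R <- spearman_cols(t(V), outcomes)
  vals <- array(NaN, dim = dim(g0$values))
  vals[midx] <- R
  structure(list(rmap = voxel_grid(vals, g0$affine), mask = cm$mask,
                 thr = thr, fraction = fraction, mirrored = mirrored),
            class = "sweetspot_map")
}

#' @export
print.sweetspot_map <- function(x, ...) {
  rng <- range(x$rmap$values[x$mask], na.rm = TRUE)
  cat("sweetspot_map: ", sum(x$mask), " voxels in mask, R in [",
      signif(rng[1L], 3), ", ", signif(rng[2L], 3), "]",
      if (x$mirrored) ", mirrored", "\n", sep = "")
  invisible(x)
}

#' Estimate an outcome score from a sweetspot map
#'
#' Mean over masked voxels of (E-field magnitude x map R): fields peaking on
#' sweet voxels score high, fields peaking on sour voxels low or negative.
#'
#' @param map a [fit_sweetspot()] result.
#' @param E an [efield_image()] on the same grid.
#' @return scalar sweetspot score.
#' @export
score_efield_map <- function(map, E) {
  stopifnot(inherits(map, "sweetspot_map"), inherits(E, "efield_image"))
  if (!same_grid(map$rmap, E$grid)) stop("grid mismatch")
  midx <- which(map$mask)
  if (!length(midx)) stop("no masked voxels")
  mean(E$grid$values[midx] * map$rmap$values[midx])
}

#' Extract sweet and sour clusters
#'
#' Connected components of {R > 0} (sweet) and {R < 0} (sour), by default
#' with 26-connectivity, split at the mid-sagittal plane so components are
#' reported per hemisphere. Each cluster reports its peak-|R| voxel (ties:
#' lowest linear index) and its |R|-weighted (or unweighted) centre of
#' gravity, both in world mm.
#'
#' @param map a [fit_sweetspot()] result.
#' @param connectivity 26 (default) or 6.
#' @param weighted_cog weight the centre of gravity by |R| (default TRUE).
#' @return data.frame of class `cluster_report`: `sign`, `hemisphere`,
#'   `n_voxels`, `peak_R`, `peak_x/y/z`, `cog_x/y/z`, sorted by decreasing
#'   `|peak_R|` within sign.
#' @export
extract_clusters <- function(map, connectivity = 26, weighted_cog = TRUE) {
  stopifnot(inherits(map, "sweetspot_map"), connectivity %in% c(6, 26))
  vals <- map$rmap$values
  if (!any(is.finite(vals) & vals != 0)) stop("empty map")
  rows <- list()
  for (sgn in c("sweet", "sour")) {
    sel <- is.finite(vals) & (if (sgn == "sweet") vals > 0 else vals < 0)
    if (!any(sel)) next
    # split components at x = 0 by restricting membership per hemisphere
    xs <- grid_x_coords(map$rmap)
    for (hemi in c("left", "right")) {
      hsel <- sel & (if (hemi == "left") xs < 0 else xs >= 0)
      if (!any(hsel)) next
      labs <- label_components(hsel, connectivity)
      for (comp in seq_len(max(labs))) {
        lin <- which(labs == comp)
        r <- vals[lin]
        peak_at <- lin[order(-abs(r), lin)[1L]]
        ijk <- linear_to_ijk(dim(vals), lin)
        wts <- if (weighted_cog) abs(r) else rep(1, length(r))
        xyz <- voxel_to_world(map$rmap, ijk)
        cog <- colSums(xyz * wts) / sum(wts)
        pk <- voxel_to_world(map$rmap, linear_to_ijk(dim(vals), peak_at))
        rows[[length(rows) + 1L]] <- data.frame(
          sign = sgn, hemisphere = hemi, n_voxels = length(lin),
          peak_R = vals[peak_at],
          peak_x = pk[1L], peak_y = pk[2L], peak_z = pk[3L],
          cog_x = cog[1L], cog_y = cog[2L], cog_z = cog[3L])
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$sign, -abs(out$peak_R)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cluster_report", "data.frame")
  out
}

## x world coordinate of every voxel, as an array matching the grid.
grid_x_coords <- function(grid) {
  shape <- dim(grid$values)
  A <- grid$affine
  xi <- A[1L, 1L] * (seq_len(shape[1L]) - 1L) + A[1L, 4L]
  xj <- A[1L, 2L] * (seq_len(shape[2L]) - 1L)
  xk <- A[1L, 3L] * (seq_len(shape[3L]) - 1L)
  array(outer(outer(xi, xj, `+`), xk, `+`), dim = shape)
}

linear_to_ijk <- function(shape, lin) {
  lin0 <- lin - 1L
  i <- lin0 %% shape[1L]
  j <- (lin0 %/% shape[1L]) %% shape[2L]
  k <- lin0 %/% (shape[1L] * shape[2L])
  cbind(i, j, k)
}

## Connected-component labelling of a logical 3-D array (BFS flood fill).
label_components <- function(mask, connectivity = 26) {
  shape <- dim(mask)
  offs <- neighbor_offsets(connectivity)
  labels <- array(0L, dim = shape)
  todo <- which(mask)
  nextlab <- 0L
  for (seed in todo) {
    if (labels[seed] != 0L) next
    nextlab <- nextlab + 1L
    queue <- seed
    labels[seed] <- nextlab
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      ijk <- linear_to_ijk(shape, cur)
      for (o in seq_len(nrow(offs))) {
        nb <- ijk + matrix(offs[o, ], nrow(ijk), 3L, byrow = TRUE)
        ok <- nb[, 1L] >= 0 & nb[, 1L] < shape[1L] &
              nb[, 2L] >= 0 & nb[, 2L] < shape[2L] &
              nb[, 3L] >= 0 & nb[, 3L] < shape[3L]
        if (!any(ok)) next
        lin <- 1L + nb[ok, 1L] + shape[1L] * (nb[ok, 2L] + shape[2L] * nb[ok, 3L])
        new <- lin[mask[lin] & labels[lin] == 0L]
        if (length(new)) {
          labels[new] <- nextlab
          queue <- c(queue, new)
        }
      }
      queue <- unique(queue)
    }
  }
  labels
}

neighbor_offsets <- function(connectivity) {
  if (connectivity == 6) {
    rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  } else {
    g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  }
}

#' Write a sweetspot R-map to NIfTI
#'
#' NaN voxels (outside the mask) are stored as NaN in float32.
#'
#' @param map a [fit_sweetspot()] result.
#' @param path output path.
#' @export
write_sweetspot <- function(map, path) write_nifti(map$rmap, path)
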