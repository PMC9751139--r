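## Analytic point-source E-field model, thresholding, coverage and mirroring.
##
## A full finite-element stimulation model is out of scope; what the mapping
## methods consume is only a smooth magnitude field decaying with distance
## from active contacts. In an infinite homogeneous isotropic medium the
## potential of a point current source is V(r) = I / (4 pi sigma r), and the
## field magnitude of a single source is |E|(r) = I / (4 pi sigma r^2).
## With I in mA, r in mm and sigma in S/m the expression conveniently yields
## V/mm directly. Multiple sources superpose as vectors; voxels closer than
## `clamp_mm` to a source are evaluated at the clamp radius so the
## singularity never enters the grid.

#' Point current source
#'
#' @param position world mm triple.
#' @param current source current in mA (nonzero).
#' @return object of class `point_source`.
#' @export
point_source <- function(position, current) {
  stopifnot(length(position) == 3L, is.finite(position))
  if (!is.finite(current) || current == 0) stop("current must be nonzero")
  structure(list(position = as.numeric(position), current = as.numeric(current)),
            class = "point_source")
}

#' Electric potential of superposed point sources at arbitrary points
#'
#' @param sources list of [point_source()].
#' @param points n x 3 matrix of world mm.
#' @param sigma medium conductivity in S/m.
#' @param clamp_mm distances below this are evaluated at the clamp radius.
#' @return potential in volts at each point.
#' @export
point_source_potential <- function(sources, points, sigma = 0.2, clamp_mm = 0.5) {
  check_sources(sources, sigma)
  points <- rbind_mat(points)
  v <- numeric(nrow(points))
  for (s in sources) {
    d <- sqrt((points[, 1L] - s$position[1L])^2 +
              (points[, 2L] - s$position[2L])^2 +
              (points[, 3L] - s$position[3L])^2)
    d <- pmax(d, clamp_mm)
    v <- v + s$current / (4 * pi * sigma * d)
  }
  v
}

#' E-field vector of superposed point sources at arbitrary points
#'
#' Analytic gradient of the superposed potential (negated), so that fields of
#' opposing sources cancel vectorially.
#'
#' @inheritParams point_source_potential
#' @return n x 3 matrix, V/mm per component.
#' @export
point_source_field <- function(sources, points, sigma = 0.2, clamp_mm = 0.5) {
  check_sources(sources, sigma)
  points <- rbind_mat(points)
  Evec <- matrix(0, nrow(points), 3L)
  for (s in sources) {
    dx <- points[, 1L] - s$position[1L]
    dy <- points[, 2L] - s$position[2L]
    dz <- points[, 3L] - s$position[3L]
    d <- sqrt(dx^2 + dy^2 + dz^2)
    dc <- pmax(d, clamp_mm)
    # magnitude I/(4 pi sigma dc^2), direction radial; at d = 0 direction is
    # undefined and the contribution is dropped
    scale <- ifelse(d > 0, s$current / (4 * pi * sigma * dc^2) / pmax(d, .Machine$double.xmin), 0)
    Evec <- Evec + cbind(dx, dy, dz) * scale
  }
  Evec
}

check_sources <- function(sources, sigma) {
  if (!length(sources)) stop("need at least one source")
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  ok <- vapply(sources, inherits, logical(1L), "point_source")
  if (!all(ok)) stop("sources must be point_source objects")
}

#' Simulate an E-field magnitude image on a grid
#'
#' @param sources list of [point_source()] (active contacts).
#' @param grid a [voxel_grid()] defining shape and affine of the output.
#' @param sigma conductivity in S/m (default 0.2, gray-matter order).
#' @param clamp_mm singularity clamp radius in mm.
#' @param patient_id id attached to the result.
#' @return an [efield_image()], magnitudes in V/mm.
#' @export
simulate_efield <- function(sources, grid, sigma = 0.2, clamp_mm = 0.5,
                            patient_id = NA_character_) {
  stopifnot(inherits(grid, "voxel_grid"))
  pts <- grid_coords(grid)
  Evec <- point_source_field(sources, pts, sigma = sigma, clamp_mm = clamp_mm)
  mag <- sqrt(rowSums(Evec^2))
  g <- voxel_grid(array(mag, dim = dim(grid$values)), grid$affine)
  efield_image(g, patient_id = patient_id)
}

#' Threshold an E-field magnitude image
#'
#' @param E an [efield_image()].
#' @param thr threshold in V/mm; voxels with magnitude >= thr are TRUE.
#' @return logical 3-D array.
#' @export
threshold_efield <- function(E, thr) {
  stopifnot(inherits(E, "efield_image"))
  if (!is.finite(thr) || thr <= 0) stop("threshold must be positive")
  E$grid$values >= thr
}

#' Cohort coverage mask
#'
#' A voxel enters the analysis mask if at least `fraction` of the cohort's
#' E-fields reach magnitude `thr` there (default: 20% of fields above
#' 0.2 V/mm, i.e. 200 V/m).
#'
#' @param fields list of [efield_image()] on one common grid.
#' @param thr magnitude threshold in V/mm.
#' @param fraction required cohort fraction in (0, 1].
#' @return object of class `coverage_mask`: logical array `mask` plus the
#'   parameters and grid used.
#' @export
coverage_mask <- function(fields, thr = 0.2, fraction = 0.2) {
  stopifnot(length(fields) >= 1L, fraction > 0, fraction <= 1)
  g0 <- fields[[1L]]$grid
  count <- array(0L, dim = dim(g0$values))
  for (E in fields) {
    if (!same_grid(E$grid, g0)) stop("E-fields are not on a common grid")
    count <- count + (E$grid$values >= thr)
  }
  structure(list(mask = count / length(fields) >= fraction,
                 thr = thr, fraction = fraction,
                 grid = voxel_grid(array(0, dim(g0$values)), g0$affine)),
            class = "coverage_mask")
}

#' Mirror an E-field across the mid-sagittal plane
#'
#' Reflects values x -> -x in world mm. Requires the grid's world x
#' coordinate to be a function of the first voxel index alone and the set of
#' x coordinates to be symmetric about 0 (the usual template-space layout);
#' mirroring is then an exact reversal along i and an involution.
#'
#' @param E an [efield_image()].
#' @return the mirrored [efield_image()] on the same grid.
#' @export
mirror_efield <- function(E) {
  stopifnot(inherits(E, "efield_image"))
  g <- E$grid
  idx <- mirror_index(g)
  vals <- g$values[idx, , , drop = FALSE]
  efield_image(voxel_grid(vals, g$affine), patient_id = E$patient_id)
}

## Returns the i-permutation implementing x -> -x, or errors.
mirror_index <- function(grid, tol = 1e-6) {
  A <- grid$affine
  if (any(abs(A[1L, 2:3]) > tol))
    stop("grid x coordinate depends on j/k; cannot mirror")
  n <- dim(grid$values)[1L]
  xs <- A[1L, 1L] * (seq_len(n) - 1L) + A[1L, 4L]
  if (max(abs(xs + rev(xs))) > tol)
    stop("grid is not symmetric about the mid-sagittal plane x = 0")
  rev(seq_len(n))
}
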