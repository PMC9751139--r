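## Core domain types.
##
## Everything downstream lives on a VoxelGrid: a 3-D value array plus a 4x4
## affine mapping 0-based voxel indices (i, j, k) to template (MNI-style)
## world millimetres, world = affine %*% c(i, j, k, 1). No half-voxel shifts.

#' Voxel grid: a 3-D scalar array with a voxel-to-world affine
#'
#' @param values 3-D numeric array.
#' @param affine invertible 4x4 matrix; maps 0-based voxel indices to mm.
#' @return object of class `voxel_grid` with fields `values` and `affine`.
#' @export
voxel_grid <- function(values, affine = diag(4)) {
  if (length(dim(values)) != 3L) stop("values must be a 3-D array")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (abs(det(affine)) < .Machine$double.eps) stop("affine is singular")
  structure(list(values = values, affine = affine), class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("voxel_grid ", paste(dim(x$values), collapse = " x "),
      ", spacing ", paste(signif(sqrt(colSums(x$affine[1:3, 1:3]^2)), 3),
                          collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$affine - b$affine)) <= tol
}

#' Construct a regular grid from shape, spacing and centre
#'
#' Convenience constructor for axis-aligned grids centred on a world point
#' (by default the mid-sagittal origin, so that x = 0 falls midway between
#' columns of voxels or on a voxel centre depending on parity).
#'
#' @param shape integer triple of voxel counts.
#' @param spacing voxel size in mm (scalar or triple).
#' @param center world mm of the grid centre.
#' @return empty (all-zero) [voxel_grid()].
#' @export
make_grid <- function(shape, spacing = 1, center = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0L))
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- center - spacing * (shape - 1L) / 2
  affine <- diag(c(spacing, 1))
  affine[1:3, 4L] <- origin
  voxel_grid(array(0, dim = shape), affine)
}

#' World mm coordinates of every voxel
#'
#' @param grid a [voxel_grid()].
#' @return n_voxels x 3 matrix in array (column-major, i fastest) order.
#' @export
grid_coords <- function(grid) {
  shape <- dim(grid$values)
  idx <- cbind(
    rep.int(seq_len(shape[1L]) - 1L, shape[2L] * shape[3L]),
    rep.int(rep(seq_len(shape[2L]) - 1L, each = shape[1L]), shape[3L]),
    rep(seq_len(shape[3L]) - 1L, each = shape[1L] * shape[2L])
  )
  voxel_to_world(grid, idx)
}

#' Map 0-based voxel indices to world mm
#'
#' @param grid a [voxel_grid()].
#' @param ijk n x 3 matrix (or length-3 vector) of 0-based indices.
#' @return n x 3 matrix of world mm.
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- rbind_mat(ijk)
  xyz <- cbind(ijk, 1) %*% t(grid$affine)
  xyz[, 1:3, drop = FALSE]
}

#' Map world mm to nearest 0-based voxel indices
#'
#' Points falling outside the grid are flagged, not errors: callers decide
#' whether out-of-grid means "contributes zero" (fiber weighting) or a
#' problem.
#'
#' @param grid a [voxel_grid()].
#' @param xyz n x 3 matrix (or length-3 vector) of world mm.
#' @return list with `ijk` (n x 3 integer matrix of 0-based indices, rounded
#'   to nearest) and `inside` (logical vector).
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- rbind_mat(xyz)
  inv <- solve(grid$affine)
  ijk_real <- cbind(xyz, 1) %*% t(inv)
  ijk <- round(ijk_real[, 1:3, drop = FALSE])
  shape <- dim(grid$values)
  inside <- ijk[, 1L] >= 0 & ijk[, 1L] < shape[1L] &
            ijk[, 2L] >= 0 & ijk[, 2L] < shape[2L] &
            ijk[, 3L] >= 0 & ijk[, 3L] < shape[3L]
  list(ijk = matrix(as.integer(ijk), ncol = 3L), inside = inside)
}

rbind_mat <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3L) else as.matrix(x)
}

## Linear (1-based, column-major) index into the value array for 0-based ijk.
voxel_linear_index <- function(grid, ijk) {
  shape <- dim(grid$values)
  1L + ijk[, 1L] + shape[1L] * (ijk[, 2L] + shape[2L] * ijk[, 3L])
}

#' Electric-field magnitude image
#'
#' A [voxel_grid()] of E-field magnitudes in V/mm, tagged with a patient id.
#' Magnitudes must be finite and non-negative.
#'
#' @param grid a [voxel_grid()] of magnitudes (V/mm).
#' @param patient_id identifier string.
#' @return object of class `efield_image`.
#' @export
efield_image <- function(grid, patient_id = NA_character_) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (any(!is.finite(grid$values))) stop("non-finite E-field magnitude")
  if (any(grid$values < 0)) stop("negative E-field magnitude")
  structure(list(grid = grid, patient_id = as.character(patient_id),
                 units = "V/mm"),
            class = "efield_image")
}

#' @export
print.efield_image <- function(x, ...) {
  cat("efield_image [", x$patient_id, "] max ",
      signif(max(x$grid$values), 4), " V/mm\n", sep = "")
  print(x$grid)
  invisible(x)
}

#' Load an E-field magnitude volume from NIfTI
#'
#' @param path NIfTI file containing a 3-D non-negative magnitude volume.
#' @param patient_id identifier attached to the image.
#' @return an [efield_image()].
#' @export
load_efield <- function(path, patient_id = NA_character_) {
  efield_image(read_nifti(path), patient_id = patient_id)
}

#' Write an E-field image to NIfTI
#'
#' @param E an [efield_image()].
#' @param path output path.
#' @export
write_efield <- function(E, path) write_nifti(E$grid, path)
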