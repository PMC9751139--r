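## DBS network mapping on a voxel-timeseries connectome.
##
## A connectome is a brain mask plus one BOLD-like timeseries per masked
## voxel (group-averaged normative data in the real setting). Seeding from a
## patient's E-field means averaging masked voxel timeseries weighted by the
## field magnitude; correlating that seed series with every voxel series and
## Fisher-z-transforming yields the patient's connectivity fingerprint.
## Voxel-wise Spearman correlation of fingerprints with outcomes gives the
## R-map of optimal connectivity; held-out fingerprints are scored by their
## spatial rank correlation with the R-map.

#' Connectome: brain mask plus per-voxel timeseries
#'
#' @param mask logical 3-D array (or [voxel_grid()] with 0/1 values).
#' @param series n_masked_voxels x T numeric matrix, rows in mask scan order
#'   (column-major, i fastest); every row must have nonzero variance.
#' @param affine 4x4 voxel-to-world affine for the mask grid.
#' @return object of class `connectome`.
#' @export
connectome <- function(mask, series, affine = diag(4)) {
  if (inherits(mask, "voxel_grid")) {
    affine <- mask$affine
    mask <- mask$values != 0
  }
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, is.matrix(series))
  if (nrow(series) != sum(mask))
    stop("series rows must equal masked voxel count")
  if (ncol(series) < 20L) stop("need at least 20 time samples")
  if (any(!is.finite(series))) stop("non-finite timeseries")
  sds <- apply(series, 1L, stats::sd)
  if (any(sds == 0)) stop("constant timeseries at ", sum(sds == 0), " voxel(s)")
  structure(list(mask = mask, series = series, affine = as.matrix(affine)),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat("connectome: ", nrow(x$series), " voxels x ", ncol(x$series),
      " samples\n", sep = "")
  invisible(x)
}

#' Seed-based connectivity fingerprint of an E-field
#'
#' Seed series = E-magnitude-weighted average of masked voxel series
#' (weights normalise, so scaling the field changes nothing); fingerprint =
#' Fisher-z of the Pearson correlation between the seed and every masked
#' voxel's series. `binary_seed` uses equal weights over the field's
#' suprathreshold voxels instead.
#'
#' @param E an [efield_image()] on the connectome's grid.
#' @param conn a [connectome()].
#' @param binary_seed use a binary stimulation-volume seed at `thr` V/mm.
#' @param thr threshold for the binary seed.
#' @return object of class `fingerprint`: `z` (per-masked-voxel Fisher-z),
#'   `patient_id`.
#' @export
compute_fingerprint <- function(E, conn, binary_seed = FALSE, thr = 0.2) {
  stopifnot(inherits(E, "efield_image"), inherits(conn, "connectome"))
  if (!identical(dim(E$grid$values), dim(conn$mask)))
    stop("E-field and connectome mask are not on one grid")
  w <- E$grid$values[conn$mask]
  if (binary_seed) w <- as.numeric(w >= thr)
  if (sum(w) <= 0) stop("E-field has no overlap with the connectome mask")
  seed <- as.vector(crossprod(conn$series, w / sum(w)))
  r <- as.vector(stats::cor(seed, t(conn$series)))
  structure(list(z = fisher_z(r), patient_id = E$patient_id),
            class = "fingerprint")
}

#' Fit the network R-map
#'
#' @param fingerprints list of [compute_fingerprint()] results on one mask.
#' @param outcomes percentage improvement aligned with `fingerprints`.
#' @return object of class `network_rmap`: per-masked-voxel Spearman `R`.
#' @export
fit_rmap <- function(fingerprints, outcomes) {
  if (length(fingerprints) < 3L) stop("need at least 3 fingerprints")
  if (length(fingerprints) != length(outcomes))
    stop("fingerprints/outcomes length mismatch")
  if (stats::sd(outcomes) == 0) stop("zero outcome variance")
  nz <- length(fingerprints[[1L]]$z)
  Z <- vapply(fingerprints, function(f) {
    if (length(f$z) != nz) stop("fingerprint mask mismatch")
    f$z
  }, numeric(nz))
  structure(list(R = spearman_cols(t(Z), outcomes)), class = "network_rmap")
}

#' Score a fingerprint against an R-map
#'
#' Spatial Spearman correlation over masked voxels between the fingerprint's
#' Fisher-z values and the R-map.
#'
#' @param rmap a [fit_rmap()] result.
#' @param fp a [compute_fingerprint()] result on the same mask.
#' @return scalar network score.
#' @export
score_fingerprint <- function(rmap, fp) {
  stopifnot(inherits(rmap, "network_rmap"), inherits(fp, "fingerprint"))
  if (length(fp$z) != length(rmap$R)) stop("mask mismatch")
  suppressWarnings(stats::cor(fp$z, rmap$R, method = "spearman"))
}

#' Decode an R-map against a library of term maps
#'
#' Spatial similarity between the fitted R-map and each named map in the
#' library (e.g. meta-analytic term maps resampled to the same mask), ranked
#' descending. Pearson similarity (the default) weights the informative
#' high-|value| voxels; rank-based similarity is offered as an alternative
#' (it is invariant to any positive affine rescaling of the term maps, but
#' over masks dominated by near-zero background it is governed by the
#' spatial ordering of that background).
#'
#' @param rmap a [fit_rmap()] result.
#' @param term_maps named list of per-masked-voxel numeric vectors.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param stoplist character vector of term names to drop before ranking.
#' @return data.frame with `term` and `similarity`, sorted descending.
#' @export
decode_rmap <- function(rmap, term_maps, method = c("pearson", "spearman"),
                        stoplist = character(0)) {
  method <- match.arg(method)
  stopifnot(inherits(rmap, "network_rmap"))
  term_maps <- term_maps[setdiff(names(term_maps), stoplist)]
  if (!length(term_maps)) stop("empty term-map library")
  sim <- vapply(term_maps, function(m) {
    if (length(m) != length(rmap$R)) stop("term map mask mismatch")
    suppressWarnings(stats::cor(m, rmap$R, method = method))
  }, numeric(1L))
  out <- data.frame(term = names(term_maps), similarity = as.numeric(sim),
                    stringsAsFactors = FALSE)
  out[order(-out$similarity), , drop = FALSE]
}

#' Write a connectome to disk
#'
#' Mask as NIfTI, timeseries as a flat little-endian float64 binary matrix
#' (voxel rows in mask scan order, time fastest), plus a JSON sidecar with
#' dimensions.
#'
#' @param conn a [connectome()].
#' @param prefix output path prefix; writes `<prefix>_mask.nii`,
#'   `<prefix>_series.bin`, `<prefix>.json`.
#' @export
write_connectome <- function(conn, prefix) {
  mask_grid <- voxel_grid(array(as.numeric(conn$mask), dim(conn$mask)),
                          conn$affine)
  write_nifti(mask_grid, paste0(prefix, "_mask.nii"))
  con <- file(paste0(prefix, "_series.bin"), "wb")
  writeBin(as.vector(t(conn$series)), con, size = 8L, endian = "little")
  close(con)
  jsonlite::write_json(list(n_voxels = nrow(conn$series),
                            n_samples = ncol(conn$series),
                            order = "voxel-major, time fastest",
                            dtype = "float64le"),
                       paste0(prefix, ".json"), auto_unbox = TRUE)
  invisible(prefix)
}

#' Read a connectome written by [write_connectome()]
#' @param prefix path prefix used when writing.
#' @return a [connectome()].
#' @export
read_connectome <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"))
  mask_grid <- read_nifti(paste0(prefix, "_mask.nii"))
  con <- file(paste0(prefix, "_series.bin"), "rb")
  vals <- readBin(con, "double", meta$n_voxels * meta$n_samples, size = 8L,
                  endian = "little")
  close(con)
  series <- matrix(vals, nrow = meta$n_voxels, byrow = TRUE)
  connectome(mask_grid$values != 0, series, affine = mask_grid$affine)
}
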