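## Minimal NIfTI-1 I/O.
##
## Only what the pipeline needs: 3-D scalar volumes, sform/qform affines, the
## common numeric datatypes, scl_slope/scl_inter scaling, gzip, and both byte
## orders. Written volumes are always float32 with sform_code = 1 (aligned),
## which is how template-space derivatives are exchanged in practice.

NIFTI_DT <- list(
  `2`    = list(what = "integer", size = 1L, signed = FALSE), # uint8
  `4`    = list(what = "integer", size = 2L, signed = TRUE),  # int16
  `8`    = list(what = "integer", size = 4L, signed = TRUE),  # int32
  `16`   = list(what = "double",  size = 4L, signed = TRUE),  # float32
  `64`   = list(what = "double",  size = 8L, signed = TRUE),  # float64
  `256`  = list(what = "integer", size = 1L, signed = TRUE),  # int8
  `512`  = list(what = "integer", size = 2L, signed = FALSE)  # uint16
)

nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a 3-D NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [voxel_grid()] carrying the value array and the voxel-to-world
#'   affine (sform if present, otherwise qform, otherwise a pixdim diagonal).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  first <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  endian <- if (first == 348L) "little"
            else if (first == 1543503872L) "big"  # 348 byte-swapped
            else stop("not a NIfTI-1 file (sizeof_hdr = ", first, ")")
  hdr <- readBin(con, "raw", 344L)
  if (length(hdr) < 344L) stop("corrupt NIfTI header (truncated)")
  # hdr[1] is file offset 4; field at file offset `off` starts at hdr[off - 3]
  rd_i16 <- function(off, n) readBin(hdr[(off - 3L):344L], "integer", n,
                                     size = 2L, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr[(off - 3L):344L], "double", n,
                                     size = 4L, endian = endian)
  magic <- rawToChar(hdr[(344L - 3L):(346L - 3L)])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic)")

  dim <- rd_i16(40L, 8L)
  ndim <- dim[1L]
  if (ndim < 3L) stop("expected a 3-D volume, got ", ndim, " dimensions")
  if (ndim > 3L && any(dim[5:(ndim + 1L)] > 1L))
    stop("expected a 3-D volume, got dim = ",
         paste(dim[2:(ndim + 1L)], collapse = "x"))
  shape <- dim[2:4]

  datatype <- rd_i16(70L, 1L)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code ", datatype)
  pixdim <- rd_f32(76L, 8L)
  vox_offset <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L)
  scl_inter <- rd_f32(116L, 1L)
  qform_code <- rd_i16(252L, 1L)
  sform_code <- rd_i16(254L, 1L)

  affine <- if (sform_code > 0L) {
    rbind(matrix(rd_f32(280L, 12L), nrow = 3L, byrow = TRUE), c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    quat <- rd_f32(256L, 6L)  # quatern b/c/d, qoffset x/y/z
    qfac <- if (pixdim[1L] %in% c(-1, 1)) pixdim[1L] else 1
    quaternion_affine(quat[1:3], quat[4:6], pixdim[2:4], qfac)
  } else {
    diag(c(pixdim[2:4], 1))
  }

  seek(con, where = vox_offset, origin = "start")
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop("corrupt NIfTI data (truncated)")
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  voxel_grid(array(vals, dim = shape), affine)
}

quaternion_affine <- function(bcd, offset, spacing, qfac) {
  b <- bcd[1]; c <- bcd[2]; d <- bcd[3]
  a <- sqrt(max(1 - b * b - c * c - d * d, 0))
  R <- matrix(c(
    a*a + b*b - c*c - d*d, 2*(b*c - a*d),         2*(b*d + a*c),
    2*(b*c + a*d),         a*a + c*c - b*b - d*d, 2*(c*d - a*b),
    2*(b*d - a*c),         2*(c*d + a*b),         a*a + d*d - b*b - c*c
  ), nrow = 3L, byrow = TRUE)
  S <- diag(c(spacing[1], spacing[2], spacing[3] * qfac))
  rbind(cbind(R %*% S, offset), c(0, 0, 0, 1))
}

#' Write a 3-D volume as NIfTI-1 (float32, sform)
#'
#' @param grid a [voxel_grid()].
#' @param path output path; `.gz` suffix triggers gzip.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  shape <- dim(grid$values)
  w <- function(x, size) writeBin(x, con, size = size, endian = "little")
  pad <- function(s, len) {
    r <- charToRaw(s)
    c(r[seq_len(min(length(r), len))], raw(max(0L, len - length(r))))
  }
  w(348L, 4L)                                        # sizeof_hdr
  writeBin(raw(36L), con)                            # data_type .. dim_info
  w(as.integer(c(3L, shape, 1L, 1L, 1L, 1L)), 2L)    # dim[8]
  w(c(0, 0, 0), 4L)                                  # intent_p1..p3
  w(c(0L, 16L, 32L, 0L), 2L)                         # intent_code, datatype, bitpix, slice_start
  spacing <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  w(c(1, spacing, 1, 1, 1, 1), 4L)                   # pixdim[8]
  w(352, 4L)                                         # vox_offset
  w(c(1, 0), 4L)                                     # scl_slope, scl_inter
  w(0L, 2L)                                          # slice_end
  writeBin(raw(2L), con)                             # slice_code, xyzt_units
  w(c(0, 0, 0, 0), 4L)                               # cal_max/min, slice_duration, toffset
  w(c(0L, 0L), 4L)                                   # glmax, glmin
  writeBin(pad("stimmap", 80L), con)                 # descrip
  writeBin(raw(24L), con)                            # aux_file
  w(c(0L, 1L), 2L)                                   # qform_code = 0, sform_code = 1
  w(rep(0, 6), 4L)                                   # quatern b/c/d, qoffset x/y/z
  w(as.vector(t(grid$affine[1:3, , drop = FALSE])), 4L)  # srow_x/y/z
  writeBin(raw(16L), con)                            # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)        # magic
  writeBin(raw(4L), con)                             # extension flag
  w(as.double(grid$values), 4L)
  invisible(path)
}
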