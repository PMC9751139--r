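## Tractogram container and TRK / TCK streamline I/O.
##
## Streamlines are ordered 3-D polylines in template mm (RAS). TRK files are
## written in the TrackVis v2 layout with unit voxel size and a +0.5 mm
## translation in vox_to_ras, so stored coordinates equal world mm after the
## format's half-voxel corner convention is applied. TCK is the MRtrix
## Float32LE layout, which stores world mm directly.

#' Tractogram: a set of streamlines with optional per-fiber annotations
#'
#' @param streamlines list of n x 3 numeric matrices (n >= 2), template mm.
#' @param bundle optional integer bundle label per streamline.
#' @param scalar optional numeric scalar per streamline (e.g. fitted R).
#' @return object of class `tractogram`.
#' @export
tractogram <- function(streamlines, bundle = NULL, scalar = NULL) {
  streamlines <- lapply(streamlines, function(s) {
    s <- as.matrix(s)
    if (ncol(s) != 3L) stop("streamline points must be n x 3")
    if (nrow(s) < 2L) stop("streamline must have at least 2 points")
    if (any(!is.finite(s))) stop("non-finite streamline coordinate")
    storage.mode(s) <- "double"
    s
  })
  n <- length(streamlines)
  if (!is.null(bundle) && length(bundle) != n)
    stop("bundle labels must match streamline count")
  if (!is.null(scalar) && length(scalar) != n)
    stop("per-fiber scalars must match streamline count")
  structure(list(streamlines = streamlines,
                 bundle = if (!is.null(bundle)) as.integer(bundle),
                 scalar = if (!is.null(scalar)) as.numeric(scalar)),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  cat("tractogram: ", length(x$streamlines), " streamlines",
      if (!is.null(x$bundle)) paste0(", ", length(unique(x$bundle)), " bundles"),
      "\n", sep = "")
  invisible(x)
}

#' Number of streamlines
#' @param x a [tractogram()].
#' @export
n_fibers <- function(x) length(x$streamlines)

#' Subset a tractogram by streamline index
#' @param x a [tractogram()].
#' @param idx integer or logical index.
#' @export
subset_fibers <- function(x, idx) {
  tractogram(x$streamlines[idx],
             bundle = if (!is.null(x$bundle)) x$bundle[idx],
             scalar = if (!is.null(x$scalar)) x$scalar[idx])
}

#' Load a tractogram from TRK or TCK
#'
#' @param path file path; format chosen by extension.
#' @return a [tractogram()] in template mm.
#' @export
load_tractogram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         trk = read_trk(path),
         tck = read_tck(path),
         stop("unknown tractogram extension: .", ext))
}

#' Write a tractogram to TRK or TCK
#'
#' TRK carries the per-fiber scalar (if any) as a per-tract property; TCK
#' stores coordinates only.
#'
#' @param x a [tractogram()].
#' @param path output path; format chosen by extension.
#' @export
write_tractogram <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         trk = write_trk(x, path),
         tck = write_tck(x, path),
         stop("unknown tractogram extension: .", ext))
  invisible(path)
}

## --- TRK (TrackVis) ---------------------------------------------------------

write_trk <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(v, size) writeBin(v, con, size = size, endian = "little")
  pad <- function(s, len) {
    r <- charToRaw(s); c(r[seq_len(min(length(r), len))], raw(max(0L, len - length(r))))
  }
  n_props <- if (!is.null(x$scalar)) 1L else 0L
  writeBin(pad("TRACK", 6L), con)
  w(c(1L, 1L, 1L), 2L)                     # dim (nominal)
  w(c(1, 1, 1), 4L)                        # voxel_size
  w(c(0, 0, 0), 4L)                        # origin
  w(0L, 2L)                                # n_scalars
  writeBin(raw(200L), con)                 # scalar_name[10][20]
  w(n_props, 2L)                           # n_properties
  writeBin(if (n_props) pad("fiber_R", 200L) else raw(200L), con)
  vox2ras <- diag(4); vox2ras[1:3, 4] <- 0.5  # stored = mm - 0.5 after /voxsize
  w(as.vector(t(vox2ras)), 4L)
  writeBin(raw(444L), con)                 # reserved
  writeBin(pad("RAS", 4L), con)            # voxel_order
  writeBin(raw(4L), con)                   # pad2
  w(rep(0, 6), 4L)                         # image_orientation_patient
  writeBin(raw(2L), con)                   # pad1
  writeBin(raw(6L), con)                   # invert/swap flags
  w(length(x$streamlines), 4L)             # n_count
  w(2L, 4L)                                # version
  w(1000L, 4L)                             # hdr_size
  for (i in seq_along(x$streamlines)) {
    s <- x$streamlines[[i]]
    w(nrow(s), 4L)
    # stored TRK coords: voxel-space * voxel_size with corner origin =
    # inverse of vox2ras then + 0.5; with the affine above this is mm - 0.5 + 0.5
    w(as.vector(t(s - 0.5 + 0.5)), 4L)
    if (n_props) w(x$scalar[i], 4L)
  }
  invisible(path)
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 1000L)
  if (length(hdr) < 1000L) stop("corrupt TRK header (truncated)")
  if (rawToChar(hdr[1:5]) != "TRACK") stop("corrupt TRK header (bad magic)")
  rd_i16 <- function(off, n) readBin(hdr[(off + 1L):1000L], "integer", n, size = 2L, endian = "little")
  rd_i32 <- function(off, n) readBin(hdr[(off + 1L):1000L], "integer", n, size = 4L, endian = "little")
  rd_f32 <- function(off, n) readBin(hdr[(off + 1L):1000L], "double", n, size = 4L, endian = "little")
  hdr_size <- rd_i32(996L, 1L)
  if (hdr_size != 1000L) stop("corrupt TRK header (unsupported byte order or size)")
  voxel_size <- rd_f32(12L, 3L)
  n_scalars <- rd_i16(36L, 1L)
  n_props <- rd_i16(238L, 1L)
  version <- rd_i32(992L, 1L)
  vox2ras <- matrix(rd_f32(440L, 16L), nrow = 4L, byrow = TRUE)
  if (version < 2L || vox2ras[4L, 4L] == 0) {
    vox2ras <- diag(4)  # legacy files: assume stored coords are already mm
    voxel_size <- c(1, 1, 1)
    half <- 0
  } else half <- 0.5
  n_count <- rd_i32(988L, 1L)
  streamlines <- vector("list", if (n_count > 0L) n_count else 0L)
  scalar <- if (n_props >= 1L) numeric(length(streamlines))
  i <- 0L
  repeat {
    npts <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (length(npts) == 0L) break
    i <- i + 1L
    vals <- readBin(con, "double", npts * (3L + n_scalars), size = 4L, endian = "little")
    m <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(m, 2L, voxel_size, "/") - half
    mm <- cbind(vox, 1) %*% t(vox2ras)
    streamlines[[i]] <- mm[, 1:3, drop = FALSE]
    if (n_props > 0L) {
      props <- readBin(con, "double", n_props, size = 4L, endian = "little")
      if (!is.null(scalar)) scalar[i] <- props[1L]
    }
  }
  if (n_count > 0L && i != n_count) stop("corrupt TRK file: expected ",
                                         n_count, " streamlines, read ", i)
  tractogram(streamlines[seq_len(i)], scalar = if (!is.null(scalar)) scalar[seq_len(i)])
}

## --- TCK (MRtrix) -----------------------------------------------------------

write_tck <- function(x, path) {
  hdr <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ",
                length(x$streamlines), "\n")
  # offset must include its own line; zero-padded field keeps it stable
  offset_line <- function(off) sprintf("file: . %06d\nEND\n", off)
  off <- nchar(hdr, type = "bytes") + nchar(offset_line(0L), type = "bytes")
  hdr <- paste0(hdr, offset_line(off))
  stopifnot(nchar(hdr, type = "bytes") == off)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(hdr), con)
  for (s in x$streamlines) {
    writeBin(as.vector(t(s)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
  invisible(path)
}

read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw_head <- readBin(con, "raw", 4096L)
  # locate "\nEND\n" at the raw level; the payload after it is binary
  pat <- charToRaw("\nEND\n")
  end_at <- NA_integer_
  limit <- length(raw_head) - length(pat) + 1L
  for (i in seq_len(max(limit, 0L))) {
    if (raw_head[i] == pat[1L] &&
        identical(raw_head[i:(i + 4L)], pat)) { end_at <- i; break }
  }
  if (is.na(end_at)) stop("corrupt TCK header (no END)")
  header <- rawToChar(raw_head[seq_len(end_at + 4L)])
  if (!startsWith(header, "mrtrix tracks")) stop("corrupt TCK header")
  lines <- strsplit(header, "\n", fixed = TRUE)[[1L]]
  kv <- lines[grepl(":", lines, fixed = TRUE)]
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  dtype <- vals[match("datatype", keys)]
  if (is.na(dtype) || dtype != "Float32LE")
    stop("unsupported TCK datatype: ", dtype)
  file_field <- vals[match("file", keys)]
  off <- as.integer(sub("^\\.\\s+", "", file_field))
  seek(con, where = off, origin = "start")
  floats <- readBin(con, "double", n = file.size(path), size = 4L, endian = "little")
  pts <- matrix(floats, ncol = 3L, byrow = TRUE)
  is_nan <- rowSums(is.na(pts)) == 3L
  is_inf <- is.infinite(pts[, 1L]) & is.infinite(pts[, 2L]) & is.infinite(pts[, 3L])
  stop_at <- which(is_inf)[1L]
  if (!is.na(stop_at)) pts <- pts[seq_len(stop_at - 1L), , drop = FALSE]
  breaks <- which(rowSums(is.na(pts)) == 3L)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks - 1L, nrow(pts))
  keep <- starts <= ends
  streamlines <- Map(function(a, b) pts[a:b, , drop = FALSE],
                     starts[keep], ends[keep])
  tractogram(streamlines)
}
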