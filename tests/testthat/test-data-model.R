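# Domain types, outcome derivation, coordinate mapping, volume/streamline I/O.

test_that("improvement_pct follows the baseline-denominated definition", {
  expect_equal(improvement_pct(20, 20), 0)
  expect_equal(improvement_pct(20, 10), 50)
  # arithmetic on the cohort-mean scores: change of means, not mean of changes
  expect_equal(round(improvement_pct(18.5, 23.6), 2), -27.57)
  expect_error(improvement_pct(0, 10), "positive")
  expect_error(improvement_pct(10, NaN), "non-finite")
  # identity on the defined scale
  set.seed(1)
  b <- runif(200, 5, 40); x <- runif(200, -150, 100)
  expect_equal(improvement_pct(b, b * (1 - x / 100)), x)
})

test_that("classify_responder partitions the line with the stated edges", {
  expect_equal(as.character(classify_responder(c(-21, -10.5, 0.01, 0, -20.99))),
               c("poor", "middle", "top", "middle", "middle"))
  expect_error(classify_responder(Inf), "non-finite")
  set.seed(2)
  x <- runif(1e4, -200, 200)
  cls <- classify_responder(x)
  expect_false(anyNA(cls))            # no gaps
  expect_equal(nlevels(cls), 3L)      # exhaustive three-way partition
})

test_that("world_to_voxel inverts the affine and flags out-of-grid points", {
  g <- unit_grid(c(10L, 10L, 10L))
  r <- world_to_voxel(g, c(3, 4, 5))
  expect_equal(r$ijk[1, ], c(3L, 4L, 5L), ignore_attr = TRUE)
  expect_true(r$inside)

  g2 <- make_grid(c(11L, 11L, 11L), 2, center = c(0, 0, 0))  # origin -10
  r2 <- world_to_voxel(g2, c(0, 0, 0))
  expect_equal(r2$ijk[1, ], c(5L, 5L, 5L), ignore_attr = TRUE)

  r3 <- world_to_voxel(g, c(100, 0, 0))
  expect_false(r3$inside)             # flagged, no error
  expect_error(voxel_grid(array(0, c(2, 2, 2)), matrix(0, 4, 4)), "singular")
})

test_that("NIfTI round-trip preserves values and affine", {
  path <- withr::local_tempfile(fileext = ".nii")
  expect_error(load_efield(path), "not found")

  g <- voxel_grid(array(0, c(2, 2, 2)), diag(4))
  write_nifti(g, path)
  back <- load_efield(path)
  expect_equal(back$grid$values, g$values)

  set.seed(3)
  aff <- diag(c(1.5, 2, 2.5, 1)); aff[1:3, 4] <- c(-10, -20, -5)
  vals <- array(abs(rnorm(4 * 5 * 6)), c(4L, 5L, 6L))
  write_nifti(voxel_grid(vals, aff), path)
  rt <- read_nifti(path)
  expect_equal(rt$affine, aff)                      # affine bit-exact
  expect_lt(max(abs(rt$values - vals)), 1e-6)       # float32 storage

  neg <- voxel_grid(array(c(-1, rep(0, 7)), c(2, 2, 2)), diag(4))
  write_nifti(neg, path)
  expect_error(load_efield(path), "negative E-field magnitude")
})

test_that("NIfTI interops with nibabel in both directions", {
  py <- Sys.which("python")
  tdir <- withr::local_tempdir()
  ours <- file.path(tdir, "r.nii")
  theirs <- file.path(tdir, "py.nii")
  set.seed(4)
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-8, -8, -8)
  vals <- array(abs(rnorm(3 * 4 * 5)), c(3L, 4L, 5L))
  write_nifti(voxel_grid(vals, aff), ours)
  script <- sprintf(
    "import nibabel as nib, numpy as np\nimg = nib.load('%s')\nassert np.allclose(img.affine[:3,3], [-8,-8,-8])\nassert abs(float(img.get_fdata().sum()) - %.10f) < 1e-3\nnib.save(nib.Nifti1Image(img.get_fdata().astype('float32'), img.affine), '%s')\n",
    ours, sum(vals), theirs)
  res <- system2(py, "-", input = script, stdout = TRUE, stderr = TRUE)
  expect_false(any(grepl("Error|assert", res)))
  back <- read_nifti(theirs)
  expect_equal(back$affine, aff)
  expect_lt(max(abs(back$values - vals)), 1e-6)
})

test_that("TRK and TCK round-trips preserve streamlines to format tolerance", {
  tdir <- withr::local_tempdir()
  set.seed(5)
  sl <- replicate(10, matrix(rnorm(15, sd = 20), 5, 3), simplify = FALSE)
  x <- tractogram(sl, scalar = runif(10))
  for (ext in c("trk", "tck")) {
    p <- file.path(tdir, paste0("t.", ext))
    write_tractogram(x, p)
    back <- load_tractogram(p)
    expect_equal(n_fibers(back), 10L)
    dev <- max(mapply(function(a, b) max(abs(a - b)), back$streamlines, sl))
    expect_lt(dev, 1e-4)
  }
  back_trk <- load_tractogram(file.path(tdir, "t.trk"))
  expect_equal(back_trk$scalar, x$scalar, tolerance = 1e-6)

  empty <- tractogram(list())
  for (ext in c("trk", "tck")) {
    p <- file.path(tdir, paste0("e.", ext))
    write_tractogram(empty, p)
    expect_equal(n_fibers(load_tractogram(p)), 0L)
  }
  expect_error(tractogram(list(matrix(1:3, 1, 3))), "at least 2 points")
  writeLines("x", file.path(tdir, "t.xyz"))
  expect_error(load_tractogram(file.path(tdir, "t.xyz")), "unknown")
})

test_that("TRK streamlines interop with nibabel", {
  py <- Sys.which("python")
  tdir <- withr::local_tempdir()
  p <- file.path(tdir, "x.trk")
  set.seed(6)
  sl <- replicate(4, matrix(rnorm(12, sd = 15), 4, 3), simplify = FALSE)
  write_tractogram(tractogram(sl), p)
  script <- sprintf(
    "import nibabel as nib, numpy as np\ntf = nib.streamlines.load('%s')\nassert len(tf.streamlines) == 4\nprint('%%.6f' %% float(np.abs(np.concatenate(tf.streamlines)).sum()))\n",
    p)
  out <- system2(py, "-", input = script, stdout = TRUE, stderr = TRUE)
  got <- suppressWarnings(as.numeric(out[length(out)]))
  expect_equal(got, sum(abs(do.call(rbind, sl))), tolerance = 1e-3)
})

test_that("cohort CSV round-trips and validates", {
  p <- withr::local_tempfile(fileext = ".csv")
  co <- cohort_table(c("a", "b", "c"), c(20, 18, 15), c(10, 20, 15),
                     age = c(66, 70, 64))
  write_cohort(co, p)
  back <- read_cohort(p)
  expect_equal(back$improvement, co$improvement)
  expect_error(cohort_table(c("a", "a"), c(10, 10), c(9, 9)), "duplicate")
  writeLines("id,baseline\na,10", p)
  expect_error(read_cohort(p), "missing columns")
})
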