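# Fiber filtering: weighting, inclusion, model fit, scoring.

test_that("peak_weights takes the maximum field value along each fiber", {
  vals <- array(0, c(5, 5, 5)); vals[3, 3, 3] <- 0.7
  E <- efield_from_values(vals)
  through <- tractogram(list(rbind(c(0, 2, 2), c(4, 2, 2))))  # passes (2,2,2)
  expect_equal(peak_weights(E, through), 0.7)
  miss <- tractogram(list(rbind(c(0, 0, 0), c(4, 0, 0))))
  expect_equal(peak_weights(E, miss), 0)
  zero <- efield_from_values(array(0, c(5, 5, 5)))
  expect_equal(peak_weights(zero, through), 0)
  outside <- tractogram(list(rbind(c(50, 50, 50), c(60, 60, 60))))
  expect_equal(peak_weights(E, outside), 0)   # outside the grid counts as 0
  expect_error(peak_weights(E, tractogram(list())), "empty")
})

test_that("peak_weights matches an exhaustive per-point lookup oracle", {
  set.seed(11)
  g <- make_grid(c(12L, 12L, 12L), 1.5)
  E <- efield_from_values(array(abs(rnorm(12^3)), c(12, 12, 12)), g$affine)
  sl <- replicate(50, {
    start <- runif(3, -8, 8); end <- runif(3, -8, 8)
    rbind(start, (start + end) / 2 + rnorm(3), end)
  }, simplify = FALSE)
  tract <- tractogram(sl)
  got <- peak_weights(E, tract)
  oracle <- vapply(sl, function(s) {
    pts <- resample_polyline(s, 0.75)
    wv <- world_to_voxel(E$grid, pts)
    v <- rep(0, nrow(pts))
    for (i in which(wv$inside))
      v[i] <- E$grid$values[wv$ijk[i, 1] + 1, wv$ijk[i, 2] + 1, wv$ijk[i, 3] + 1]
    max(v)
  }, numeric(1))
  expect_allclose(got, oracle)
})

test_that("filter_fibers applies the coverage rule exactly", {
  set.seed(12)
  W <- matrix(runif(28 * 40), 28, 40)
  fl <- filter_fibers(W, e_thr = 0.5, coverage_fraction = 0.2)
  oracle <- colSums(W >= 0.5) / 28 >= 0.2
  expect_identical(fl, oracle, ignore_attr = TRUE)
  # N = 28: a fiber reached in 6 of 28 volumes (21.4%) is included
  W2 <- matrix(0, 28, 1); W2[1:6, 1] <- 1
  expect_true(filter_fibers(W2, e_thr = 0.36, coverage_fraction = 0.2))
  W2[6, 1] <- 0
  expect_false(filter_fibers(W2, e_thr = 0.36, coverage_fraction = 0.2))
  expect_false(filter_fibers(matrix(0, 5, 1)))
})

test_that("fit_fiber_model assigns per-fiber Spearman R", {
  W <- cbind(c(1, 2, 3, 4), c(4, 4, 4, 4))
  m <- fit_fiber_model(W, c(10, 20, 30, 40), e_thr = 0.5, coverage_fraction = 0.2)
  expect_equal(m$R[1], 1)                       # perfect monotone
  expect_false(m$included[2])                   # zero weight variance
  expect_error(fit_fiber_model(W, c(5, 5, 5, 5)), "zero outcome variance")
  expect_error(fit_fiber_model(W, 1:3), "align")
  # 20 x 30 random instance against the rank-correlation oracle
  set.seed(13)
  Wr <- matrix(runif(20 * 30, 0, 2), 20, 30)
  y <- rnorm(20)
  mr <- fit_fiber_model(Wr, y, e_thr = 0.3, coverage_fraction = 0.2)
  for (j in which(mr$included))
    expect_allclose(mr$R[j], oracle_spearman(Wr[, j], y))
})

test_that("score_efield is the rank profile correlation with model R", {
  set.seed(14)
  W <- matrix(runif(10 * 15, 0, 2), 10, 15)
  m <- fit_fiber_model(W, rnorm(10), e_thr = 0.2, coverage_fraction = 0.2)
  Rv <- m$R[m$included]
  # weights that are a monotone transform of R score exactly 1
  w <- rep(0, 15); w[m$included] <- exp(Rv)
  expect_equal(score_efield(m, w), 1)
  w[m$included] <- -Rv
  expect_equal(score_efield(m, w), -1)
  # random field against the oracle
  wr <- runif(15)
  expect_allclose(score_efield(m, wr), oracle_spearman(wr[m$included], Rv))
  expect_error(score_efield(m, rep(1, 15)), "zero weight variance")
  expect_error(score_efield(m, 1:3), "align")
})

test_that("rank invariance: monotone transforms of magnitudes change nothing", {
  set.seed(15)
  W <- matrix(runif(12 * 20, 0, 1.5), 12, 20)
  y <- rnorm(12)
  m1 <- fit_fiber_model(W, y, e_thr = 0.3)
  # strictly increasing transform applied to all magnitudes; the inclusion
  # threshold is transformed with them
  f <- function(x) x^3 + 0.1 * x
  m2 <- fit_fiber_model(f(W), y, e_thr = f(0.3))
  expect_identical(m1$included, m2$included)
  expect_allclose(m1$R[m1$included], m2$R[m2$included])
  w <- runif(20)
  expect_allclose(score_efield(m1, w), score_efield(m1, f(w)))
})

test_that("permutation of outcomes decorrelates the fiber R profile", {
  # independent fibers so the null profile correlation is ~N(0, 1/sqrt(m));
  # bundle-structured worlds share weights within bundles, which leaves only
  # a handful of effective fibers and makes this check uninformative there
  set.seed(16)
  W <- matrix(runif(24 * 120), 24, 120)
  y <- 8 * W[, 1] + rnorm(24)
  m <- fit_fiber_model(W, y, e_thr = 0.3, coverage_fraction = 0.2)
  cors <- vapply(1:5, function(i) {
    mp <- fit_fiber_model(W, sample(y), e_thr = 0.3, coverage_fraction = 0.2)
    common <- m$included & mp$included
    cor(m$R[common], mp$R[common], method = "spearman")
  }, numeric(1))
  expect_lt(mean(abs(cors)), 0.25)
})

test_that("connected_fibers returns included fibers touched by the field", {
  vals <- array(0, c(5, 5, 5)); vals[3, 3, 3] <- 1
  E <- efield_from_values(vals)
  sl <- list(rbind(c(0, 2, 2), c(4, 2, 2)),    # through the hot voxel
             rbind(c(0, 0, 0), c(4, 0, 0)))    # misses it
  tract <- tractogram(sl, bundle = c(1L, 2L))
  W <- rbind(c(1, 0.5), c(0.8, 0.4), c(0.9, 0.45))
  m <- fit_fiber_model(W, c(1, 2, 3), e_thr = 0.3, coverage_fraction = 0.2)
  got <- connected_fibers(m, tract, E, e_thr = 0.5)
  expect_equal(n_fibers(got), 1L)
  expect_equal(got$bundle, 1L)
  zero <- efield_from_values(array(0, c(5, 5, 5)))
  expect_equal(n_fibers(connected_fibers(m, tract, zero)), 0L)
  # degenerate threshold: any included fiber with nonzero overlap
  vals2 <- array(0.01, c(5, 5, 5))
  expect_equal(n_fibers(connected_fibers(m, tract, efield_from_values(vals2),
                                         e_thr = 0)), 2L)
})
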