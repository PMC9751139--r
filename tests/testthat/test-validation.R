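# Cross-validation, permutation testing, calibration, metrics.

# A small feature world matching the methods' assumptions: a block of
# correlated signal columns (a "bundle") rides a latent exposure u that also
# drives outcomes; remaining columns are noise.
signal_world <- function(n = 16, m = 25, seed = 30, noise = 0.3, k_signal = 8) {
  set.seed(seed)
  k_signal <- min(k_signal, m - 1L)
  u <- runif(n, 0, 2)
  X <- matrix(runif(n * m, 0, 2), n, m)
  X[, seq_len(k_signal)] <- outer(u, runif(k_signal, 0.5, 1.5)) +
    matrix(rnorm(n * k_signal, sd = 0.05), n, k_signal)
  X <- pmax(X, 0)
  y <- 10 * u + rnorm(n, sd = noise)
  list(X = X, y = y)
}

test_that("loocv approaches R = 1 in the noiseless limit", {
  # profile scoring converges to the noiseless ideal as the signal bundle's
  # share of features grows; at 8 of 25 features it lands just below 1
  sw <- signal_world(noise = 0)
  cv <- loocv(sw$X, sw$y, model_spec("fibers", e_thr = 0.5, coverage_fraction = 0.2))
  expect_gt(cv$R, 0.9)
  expect_lt(cv$p, 1e-5)
  expect_equal(length(cv$score), 16L)
})

test_that("loocv runs at the minimal N = 4 and returns 4 predictions", {
  sw <- signal_world(n = 4, m = 8, k_signal = 3, noise = 0)
  cv <- loocv(sw$X, sw$y, model_spec("network"))
  expect_equal(sum(!is.na(cv$predicted)), 4L)
  expect_error(loocv(sw$X[1:3, ], sw$y[1:3], model_spec("network")), "at least 4")
})

test_that("k = N reproduces loocv per-unit scores exactly", {
  sw <- signal_world()
  spec <- model_spec("fibers", e_thr = 0.5)
  cv <- loocv(sw$X, sw$y, spec)
  kv <- kfold(sw$X, sw$y, spec, k = nrow(sw$X), seed = 99)
  expect_equal(kv$score, cv$score)
  expect_equal(kv$predicted, cv$predicted)
})

test_that("kfold partitions are seeded, near-equal and exhaustive", {
  sw <- signal_world(n = 17)
  spec <- model_spec("network")
  k1 <- kfold(sw$X, sw$y, spec, k = 5, seed = 4)
  k2 <- kfold(sw$X, sw$y, spec, k = 5, seed = 4)
  expect_identical(k1$fold, k2$fold)
  expect_identical(k1$score, k2$score)
  sizes <- table(k1$fold)
  expect_lte(max(sizes) - min(sizes), 1L)         # near-equal folds
  expect_equal(sort(unique(k1$fold)), 1:5)        # union of folds = cohort
  expect_error(kfold(sw$X, sw$y, spec, k = 18, seed = 1), "exceeds")
  k3 <- kfold(sw$X, sw$y, spec, k = 5, seed = 5)
  expect_false(identical(k1$fold, k3$fold))
})

test_that("kfold R is stable relative to loocv on a strong-signal world", {
  sw <- signal_world(n = 24, m = 30, seed = 31, noise = 1)
  spec <- model_spec("fibers", e_thr = 0.5)
  cv <- loocv(sw$X, sw$y, spec)
  kv <- kfold(sw$X, sw$y, spec, k = 5, seed = 7)
  expect_lt(abs(kv$R - cv$R), 0.15)
})

test_that("loocv on permuted outcomes is usually non-significant", {
  sw <- signal_world(n = 20, m = 30, seed = 32)
  spec <- model_spec("fibers", e_thr = 0.5)
  ps <- vapply(1:20, function(s) {
    set.seed(s + 300)
    loocv(sw$X, sample(sw$y), spec)$p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("permutation_test applies the one-sided add-one rule", {
  sw <- signal_world(noise = 0)
  spec <- model_spec("fibers", e_thr = 0.5)
  pt <- permutation_test(sw$X, sw$y, spec, n_perm = 999, seed = 8)
  expect_equal(pt$p, 1 / 1000)           # observed beats every null draw
  expect_equal(length(pt$null), 999L)
  expect_gt(pt$observed, 0.95)
  expect_error(permutation_test(sw$X, sw$y, spec, n_perm = 50), "n_perm")
  # duplicated cohort rows leave the observed statistic unchanged
  pt2 <- permutation_test(rbind(sw$X, sw$X), c(sw$y, sw$y), spec,
                          n_perm = 99, seed = 8)
  expect_equal(pt2$observed, pt$observed, tolerance = 1e-12)
})

test_that("permutation p is never zero and reproducible under one seed", {
  sw <- signal_world(n = 10, m = 8, seed = 33)
  spec <- model_spec("network")
  a <- permutation_test(sw$X, sw$y, spec, n_perm = 199, seed = 5)
  b <- permutation_test(sw$X, sw$y, spec, n_perm = 199, seed = 5)
  expect_identical(a$null, b$null)
  expect_gt(a$p, 0)
})

test_that("calibrate solves the normal equations", {
  set.seed(34)
  s <- rnorm(50); y <- 3.5 * s - 12 + rnorm(50, sd = 0.5)
  cal <- calibrate(s, y)
  fit <- coef(lm(y ~ s))
  expect_allclose(c(cal$intercept, cal$slope), unname(fit), tol = 1e-10)
  expect_equal(predict_calibrated(calibrate(1:5, 1:5), 3), 3)  # identity map
  expect_error(calibrate(c(1, 2), c(1, 2)), "at least 3")
  expect_error(calibrate(rep(1, 5), 1:5), "zero score variance")
})

test_that("prediction_metrics reproduces the hand-computed example", {
  actual <- c(0, 10, 20, 30, 40)
  predicted <- c(5, 5, 25, 25, 45)
  m <- prediction_metrics(predicted, actual)
  err <- predicted - actual                       # 5 -5 5 -5 5
  expect_equal(m$RMS, sqrt(mean(err^2)))
  expect_equal(m$RMS, 5)
  expect_equal(m$MAE, 5)                          # MEDIAN absolute error
  expect_equal(m$R2_sse, 1 - sum(err^2) / sum((actual - 20)^2))
  # exact prediction and constant-mean prediction
  e <- prediction_metrics(actual, actual)
  expect_equal(c(e$R, e$RMS, e$MAE, e$R2_sse), c(1, 0, 0, 1))
  cm <- prediction_metrics(rep(20, 5), actual)
  expect_true(is.nan(cm$R))
  expect_equal(cm$R2_sse, 0)
  expect_error(prediction_metrics(1:3, 1:4), "length mismatch")
})

test_that("metrics are permutation-equivariant", {
  set.seed(35)
  a <- rnorm(12); p <- a + rnorm(12)
  o <- sample(12)
  m1 <- prediction_metrics(p, a)
  m2 <- prediction_metrics(p[o], a[o])
  expect_equal(m1[c("R", "RMS", "MAE", "R2_sse")], m2[c("R", "RMS", "MAE", "R2_sse")])
})

test_that("degenerate training folds error out", {
  X <- matrix(runif(20), 5, 4)
  expect_error(loocv(X, rep(3, 5), model_spec("network")), "zero outcome variance")
})
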