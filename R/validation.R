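## Cross-validation, permutation testing and prediction metrics.
##
## All three mapping levels reduce to the same shape: a patients x features
## matrix (fiber weights, masked voxel magnitudes, or fingerprint z-values),
## a mass-univariate Spearman fit over columns, and a per-patient scalar
## score. The validation machinery is written against that shape once, via a
## `model_spec` that names the level and its parameters.
##
## Note on "MAE": throughout this package MAE is the MEDIAN absolute error,
## which is less sensitive to outliers than the mean; the initialism is kept
## for continuity with the field's reports but never denotes the mean.

#' Model specification for a mapping level
#'
#' @param level `"fibers"`, `"sweetspot"` or `"network"`.
#' @param e_thr,coverage_fraction fiber inclusion rule (fibers level).
#' @param positive_only fibers level: score against positive-R fibers only.
#' @param thr,fraction coverage mask rule (sweetspot level).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(level = c("fibers", "sweetspot", "network"),
                       e_thr = 0.36, coverage_fraction = 0.20,
                       positive_only = FALSE, thr = 0.2, fraction = 0.2) {
  level <- match.arg(level)
  structure(list(level = level, e_thr = e_thr,
                 coverage_fraction = coverage_fraction,
                 positive_only = positive_only, thr = thr, fraction = fraction),
            class = "model_spec")
}

## Columns that enter the model, independent of outcomes.
ms_columns <- function(spec, X) {
  colvar <- apply(X, 2L, stats::sd) > 0
  sel <- switch(spec$level,
    fibers = filter_fibers(X, spec$e_thr, spec$coverage_fraction) & colvar,
    sweetspot = colMeans(X >= spec$thr) >= spec$fraction & colvar,
    network = colvar)
  if (!any(sel)) stop("no usable features (empty mask / all fibers excluded)")
  sel
}

## Fit: per-column Spearman R over the selected columns.
ms_fit <- function(spec, X, y) {
  if (stats::sd(y) == 0) stop("zero outcome variance in training fold")
  sel <- ms_columns(spec, X)
  R <- spearman_cols(X[, sel, drop = FALSE], y)
  keep <- !is.na(R)  # columns constant within this training fold
  if (spec$level == "fibers" && spec$positive_only) keep <- keep & R > 0
  sel[sel] <- keep
  list(sel = sel, R = R[keep])
}

## Score rows of X under a fitted model; NA for degenerate rows.
ms_score <- function(spec, model, X) {
  Xs <- X[, model$sel, drop = FALSE]
  if (spec$level == "sweetspot") {
    as.vector(Xs %*% ifelse(is.na(model$R), 0, model$R)) / ncol(Xs)
  } else {
    spearman_rows(Xs, model$R)
  }
}

#' Leave-one-out cross-validation
#'
#' For each patient: fit on the remaining N-1, score the held-out patient,
#' and map the score to the percent scale with an affine calibration
#' ([calibrate()]) fitted on the training fold's in-sample scores.
#'
#' @param X patients x features matrix for the level (fiber weight matrix,
#'   flattened field magnitudes, or fingerprint z matrix).
#' @param outcomes percentage improvement per row.
#' @param spec a [model_spec()].
#' @return object of class `cv_result`: per-unit `score` and `predicted`,
#'   pooled metrics (`R`, `p`, `RMS`, `MAE`, `R2_sse`), `fold`, `seed`.
#' @export
loocv <- function(X, outcomes, spec) {
  stopifnot(is.matrix(X), nrow(X) == length(outcomes))
  if (nrow(X) < 4L) stop("need at least 4 patients")
  cv_run(X, outcomes, spec, fold = seq_len(nrow(X)), seed = NA_integer_)
}

#' k-fold cross-validation
#'
#' Seeded shuffle followed by a contiguous split into k near-equal folds
#' (sizes differ by at most one; remainders go to the first folds); no
#' stratification. `k = N` reproduces the leave-one-out per-unit scores.
#'
#' @inheritParams loocv
#' @param k number of folds (2 <= k <= N).
#' @param seed integer seed for the partition.
#' @return a `cv_result`, see [loocv()].
#' @export
kfold <- function(X, outcomes, spec, k, seed = 1L) {
  n <- nrow(X)
  stopifnot(is.matrix(X), n == length(outcomes))
  if (k > n) stop("k exceeds cohort size")
  if (k < 2L) stop("need k >= 2")
  perm <- sample_with_seed(seed, n)
  sizes <- rep(n %/% k, k)
  rem <- n %% k
  if (rem) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), sizes)
  cv_run(X, outcomes, spec, fold = fold, seed = as.integer(seed))
}

sample_with_seed <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(n)
}

cv_run <- function(X, outcomes, spec, fold, seed) {
  n <- nrow(X)
  score <- rep(NA_real_, n)
  predicted <- rep(NA_real_, n)
  for (f in unique(fold)) {
    test <- which(fold == f)
    train <- setdiff(seq_len(n), test)
    model <- ms_fit(spec, X[train, , drop = FALSE], outcomes[train])
    train_scores <- ms_score(spec, model, X[train, , drop = FALSE])
    score[test] <- ms_score(spec, model, X[test, , drop = FALSE])
    cal <- calibrate(train_scores, outcomes[train])
    predicted[test] <- predict_calibrated(cal, score[test])
  }
  metrics <- prediction_metrics(predicted, outcomes)
  ok <- !is.na(score)
  rho <- suppressWarnings(stats::cor(score[ok], outcomes[ok], method = "spearman"))
  # one-sided (better-than-chance) p: held-out scores have a negative null
  # bias, so a two-sided test would be anticonservative under permutation
  tstat <- rho * sqrt((sum(ok) - 2) / max(1 - rho^2, .Machine$double.eps))
  p1 <- stats::pt(tstat, df = sum(ok) - 2, lower.tail = FALSE)
  structure(list(score = score, predicted = predicted,
                 R = rho, p = p1,
                 RMS = metrics$RMS, MAE = metrics$MAE,
                 R2_sse = metrics$R2_sse,
                 fold = fold, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result (", length(unique(x$fold)), " folds): R = ",
      signif(x$R, 3), ", p = ", signif(x$p, 3), ", RMS = ",
      signif(x$RMS, 4), ", MAE = ", signif(x$MAE, 4), "\n", sep = "")
  invisible(x)
}

#' Permutation test of the in-sample fit/score correlation
#'
#' Observed statistic: fit on the full cohort, score every patient, Spearman
#' correlation of scores with outcomes. Null draws repeat this after
#' shuffling outcomes. One-sided p with the add-one rule:
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`, so p is never 0.
#'
#' @inheritParams loocv
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed for the shuffles.
#' @return object of class `permutation_result`: `observed`, `null` (length
#'   `n_perm`), `p`, `n_perm`, `seed`.
#' @export
permutation_test <- function(X, outcomes, spec, n_perm = 1000L, seed = 1L) {
  stopifnot(is.matrix(X), nrow(X) == length(outcomes))
  if (n_perm < 99L) stop("need n_perm >= 99")
  sel <- ms_columns(spec, X)
  Xs <- X[, sel, drop = FALSE]
  colranks <- rank_cols(Xs)
  rowranks <- if (spec$level != "sweetspot") rank_cols(t(Xs))
  stat <- function(y) {
    R <- spearman_cols(Xs, y, xr = colranks)
    scores <- if (spec$level == "sweetspot") {
      as.vector(Xs %*% ifelse(is.na(R), 0, R)) / ncol(Xs)
    } else {
      if (spec$level == "fibers" && spec$positive_only) {
        keep <- !is.na(R) & R > 0
        spearman_rows(Xs[, keep, drop = FALSE], R[keep])
      } else {
        spearman_rows(Xs, R, xr = rowranks)
      }
    }
    suppressWarnings(stats::cor(scores, y, method = "spearman"))
  }
  observed <- stat(outcomes)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) stat(sample(outcomes)), numeric(1L))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  p <- (1 + sum(null >= observed, na.rm = TRUE)) / (n_perm + 1)
  structure(list(observed = observed, null = null, p = p,
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation_result: observed R = ", signif(x$observed, 3),
      ", p = ", signif(x$p, 4), " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}

#' Affine score-to-percent calibration
#'
#' Models emit unitless scores; error metrics are reported on the percent
#' improvement scale. A least-squares affine map fitted on training scores
#' bridges the two.
#'
#' @param train_scores,train_outcomes aligned numeric vectors (>= 3 points,
#'   score variance > 0).
#' @return object of class `calibration` with `intercept` and `slope`.
#' @export
calibrate <- function(train_scores, train_outcomes) {
  stopifnot(length(train_scores) == length(train_outcomes))
  if (length(train_scores) < 3L) stop("need at least 3 calibration points")
  ok <- !is.na(train_scores)
  if (sum(ok) < 3L) stop("need at least 3 calibration points")
  if (stats::sd(train_scores[ok]) == 0) stop("zero score variance")
  fit <- stats::lm.fit(cbind(1, train_scores[ok]), train_outcomes[ok])
  structure(list(intercept = unname(fit$coefficients[1L]),
                 slope = unname(fit$coefficients[2L])),
            class = "calibration")
}

#' Apply a calibration to scores
#' @param cal a [calibrate()] result.
#' @param scores numeric vector.
#' @export
predict_calibrated <- function(cal, scores) cal$intercept + cal$slope * scores

#' Prediction metrics on the percent scale
#'
#' Spearman R with two-sided t-approximation p, root-mean-square error,
#' MEDIAN absolute error, and a sum-of-squares coefficient of determination
#' `R2_sse = 1 - SSE/SST` (not the squared correlation; can be negative).
#'
#' @param predicted,actual aligned numeric vectors (length >= 3).
#' @return list with `R`, `p`, `RMS`, `MAE`, `R2_sse`, `n`.
#' @export
prediction_metrics <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  if (length(actual) < 3L) stop("need at least 3 pairs")
  err <- predicted - actual
  sst <- sum((actual - mean(actual))^2)
  rho <- suppressWarnings(stats::cor(predicted, actual, method = "spearman"))
  list(R = if (is.na(rho)) NaN else rho,
       p = if (is.na(rho)) NaN else spearman_pvalue(rho, length(actual)),
       RMS = sqrt(mean(err^2)),
       MAE = stats::median(abs(err)),
       R2_sse = 1 - sum(err^2) / sst,
       n = length(actual))
}
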