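# Shared miniature fixtures, built in code at test time.

# Small cohort world used by several module tests (kept small; the
# full-size defaults are exercised in test-acceptance.R).
tiny_cohort_spec <- function(n = 12) cohort_spec(n_patients = n)

# A grid with identity-ish affine for hand-computable lookups.
unit_grid <- function(shape = c(5L, 5L, 5L)) {
  voxel_grid(array(0, shape), diag(4))
}

# An E-field image holding given values on a grid (bypasses simulation).
efield_from_values <- function(values, affine = diag(4), id = "T") {
  efield_image(voxel_grid(values, affine), patient_id = id)
}

# Brute-force Spearman, one pair at a time (the oracle used everywhere).
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# ROC AUC by pairwise comparison (used by recovery tests).
pairwise_auc <- function(pos, neg) {
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

expect_allclose <- function(x, y, tol = 1e-12) {
  expect_true(max(abs(x - y)) < tol)
}
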