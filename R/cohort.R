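## Cohort table, outcome derivation and responder classes.
##
## Outcomes are percentage improvements on the ADAS-cog 11 scale (a deficit
## score: higher = worse cognition). The package fixes one orientation once:
## POSITIVE improvement_pct means cognitive improvement, i.e. the follow-up
## ADAS-cog score decreased relative to baseline.

#' Percentage clinical improvement from baseline and follow-up deficit scores
#'
#' `100 * (baseline - followup) / baseline`. Positive values mean the deficit
#' score dropped (improvement); negative values mean worsening. Baseline
#' denominates the change.
#'
#' @param baseline,followup ADAS-cog 11 scores (baseline must be > 0).
#' @return improvement in percent (vectorised).
#' @export
improvement_pct <- function(baseline, followup) {
  if (any(!is.finite(baseline)) || any(!is.finite(followup)))
    stop("non-finite score")
  if (any(baseline <= 0)) stop("baseline score must be positive")
  100 * (baseline - followup) / baseline
}

#' Responder class from percentage improvement
#'
#' Visualization-only partition of the improvement scale:
#' `poor` (worsening of 21% or more, improvement <= -21), `middle`
#' (worsening between 0 and 20.99%, -21 < improvement <= 0) and `top`
#' (any improvement, > 0).
#'
#' @param improvement improvement in percent (vectorised).
#' @return factor with levels `poor`, `middle`, `top`.
#' @export
classify_responder <- function(improvement) {
  if (any(!is.finite(improvement))) stop("non-finite improvement")
  cls <- ifelse(improvement <= -21, "poor",
                ifelse(improvement <= 0, "middle", "top"))
  factor(cls, levels = c("poor", "middle", "top"))
}

#' Cohort table constructor
#'
#' @param id unique patient identifiers.
#' @param baseline,followup ADAS-cog 11 scores; baseline > 0.
#' @param age years (optional, NA allowed).
#' @param efield_path per-patient E-field NIfTI reference (optional).
#' @return data.frame of class `cohort_table` with an `improvement` column
#'   derived via [improvement_pct()].
#' @export
cohort_table <- function(id, baseline, followup, age = NA_real_,
                         efield_path = NA_character_) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate patient ids")
  out <- data.frame(id = id,
                    baseline = as.numeric(baseline),
                    followup = as.numeric(followup),
                    improvement = improvement_pct(baseline, followup),
                    age = as.numeric(age),
                    efield_path = as.character(efield_path),
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Read and validate a cohort CSV
#'
#' Expected columns: `id, baseline, followup, age, efield_path` (header row
#' required; `age` and `efield_path` may be empty).
#'
#' @param path CSV file path.
#' @return a [cohort_table()].
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "baseline", "followup")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("cohort CSV missing columns: ",
                            paste(missing, collapse = ", "))
  cohort_table(df$id, df$baseline, df$followup,
               age = if ("age" %in% names(df)) df$age else NA_real_,
               efield_path = if ("efield_path" %in% names(df))
                 df$efield_path else NA_character_)
}

#' Write a cohort table to CSV
#' @param cohort a [cohort_table()].
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort[, c("id", "baseline", "followup", "age", "efield_path")],
                   path, row.names = FALSE)
  invisible(path)
}
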