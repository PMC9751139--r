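## Binary-event (flashback) fiber filtering with FDR control.
##
## During intraoperative testing, many stimulation settings (probes) are
## tried per patient and a rare binary event — a stimulation-evoked
## autobiographical "flashback" episode — is recorded per probe. Probes, not
## patients, are the unit of analysis; within-patient dependence is left
## unmodelled, matching the field's practice. Per fiber, the Spearman (rank
## point-biserial) correlation between probe weights and the 0/1 event
## vector is tested two-sided and controlled by Benjamini-Hochberg FDR.

#' Probe set constructor
#'
#' @param patient patient id per probe.
#' @param contact contact index per probe.
#' @param amplitude stimulation amplitude per probe (mA).
#' @param event logical: did this probe evoke a flashback episode.
#' @param intensity optional event-intensity score (e.g. TEMPau); carried
#'   through I/O, not used by the default binary contrast.
#' @param efield_path optional per-probe E-field reference.
#' @return data.frame of class `probe_set`.
#' @export
probe_set <- function(patient, contact, amplitude, event,
                      intensity = NA_real_, efield_path = NA_character_) {
  event <- as.logical(event)
  if (any(is.na(event))) stop("event flags must be TRUE/FALSE")
  out <- data.frame(patient = as.character(patient),
                    contact = as.integer(contact),
                    amplitude = as.numeric(amplitude),
                    event = event,
                    intensity = as.numeric(intensity),
                    efield_path = as.character(efield_path),
                    stringsAsFactors = FALSE)
  class(out) <- c("probe_set", "data.frame")
  out
}

#' Benjamini-Hochberg FDR step-up
#'
#' Rejects all hypotheses with `p <= p_(k*)` where
#' `k* = max{k : p_(k) <= k q / m}`.
#'
#' @param p p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return logical rejection flags, aligned with `p`.
#' @export
fdr_correct <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  m <- length(p)
  if (m == 0L) return(logical(0))
  o <- order(p)
  ps <- p[o]
  below <- which(ps <= seq_len(m) * q / m)
  if (!length(below)) return(rep(FALSE, m))
  p <= ps[max(below)]
}

#' Fiber filtering against binary flashback events
#'
#' @param W probes x fibers weight matrix (see [fiber_weight_matrix()] or
#'   [probe_weight_matrix()]).
#' @param events logical event flag per probe; both classes must occur.
#' @param e_thr,coverage_fraction fiber inclusion rule as in
#'   [filter_fibers()].
#' @param q FDR level.
#' @return object of class `flashback_result`: per-fiber `R`, `p` (NA where
#'   excluded), logical `significant`, `included`, and the parameters.
#' @export
fit_flashback_fibers <- function(W, events, e_thr = 0.36,
                                 coverage_fraction = 0.20, q = 0.05) {
  stopifnot(is.matrix(W), nrow(W) == length(events))
  events <- as.logical(events)
  if (!any(events) || all(events)) stop("need both event and non-event probes")
  included <- filter_fibers(W, e_thr, coverage_fraction)
  R <- rep(NA_real_, ncol(W))
  p <- rep(NA_real_, ncol(W))
  significant <- rep(FALSE, ncol(W))
  if (any(included)) {
    R[included] <- spearman_cols(W[, included, drop = FALSE], as.numeric(events))
    included <- included & !is.na(R)
    p[included] <- spearman_pvalue(R[included], nrow(W))
    significant[included] <- fdr_correct(p[included], q = q)
  }
  structure(list(R = R, p = p, significant = significant, included = included,
                 e_thr = e_thr, coverage_fraction = coverage_fraction, q = q),
            class = "flashback_result")
}

#' @export
print.flashback_result <- function(x, ...) {
  cat("flashback_result: ", sum(x$included), " fibers included, ",
      sum(x$significant), " FDR-significant at q = ", x$q, "\n", sep = "")
  invisible(x)
}
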