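#' Staircase quality control: the rising-staircase ratio rule
#'
#' The mean running threshold estimate over the final 5 trials is divided
#' by the mean over the first 10 trials. A ratio above 0.8 marks the
#' staircase as unreliable ("rising staircase"): its estimates climbed, or
#' failed to descend, late in the trial sequence. A supplementary
#' deterministic rule (standing in for ad-hoc visual inspection) separately
#' flags staircases whose running-estimate maximum occurs after trial 15
#' and exceeds twice the first-10 mean.
#'
#' @param record A [staircase_record()] with at least 15 trials.
#' @return A list with `ratio`, `flagged` (ratio rule, `ratio > 0.8`) and
#'   `late_peak` (supplementary rule, logged separately).
#' @export
staircase_qc <- function(record) {
  est <- record$trials$running_estimate_ms
  n <- length(est)
  stopifnot(n >= 15)
  first10 <- mean(est[1:10])
  last5 <- mean(est[(n - 4):n])
  if (first10 <= 0) stop("first-10 mean of running estimates is zero")
  ratio <- last5 / first10
  peak_at <- which.max(est)
  list(ratio = ratio,
       flagged = ratio > 0.8,
       late_peak = peak_at > 15 && est[peak_at] > 2 * first10)
}

#' Subject-level exclusion rule
#'
#' Counts staircases flagged by the ratio rule across all of a subject's
#' staircases; a subject with 4 or more flagged staircases is an exclusion
#' candidate.
#'
#' @param records A list of [staircase_record()]s.
#' @return A list with `n_flagged` and `exclusion_candidate`.
#' @export
subject_qc <- function(records) {
  flags <- vapply(records, function(r) staircase_qc(r)$flagged, logical(1))
  list(n_flagged = sum(flags), exclusion_candidate = sum(flags) >= 4)
}

#' Final threshold for a condition
#'
#' The exact median of the per-run threshold estimates that survived QC
#' (mean of the middle two for even counts).
#'
#' @param per_run Numeric vector of per-run thresholds (ms).
#' @return The median, or `NA_real_` (with a warning) if no run survived —
#'   a missing-condition status.
#' @export
final_threshold <- function(per_run) {
  per_run <- per_run[is.finite(per_run)]
  if (length(per_run) == 0) {
    warning("no surviving runs: condition threshold is missing")
    return(NA_real_)
  }
  stats::median(per_run)
}

#' Estimate thresholds and QC flags from a trial table
#'
#' The re-analysis entry point for trial-level psychophysics data: for each
#' subject x condition x run, fits a Weibull psychometric function by
#' maximum likelihood and reads out the duration at the criterion accuracy;
#' applies the rising-staircase ratio rule per staircase and the 4-or-more
#' rule per subject; and reports the median over surviving runs as the
#' final threshold for each condition.
#'
#' @param trials Data frame with columns `subject_id`, `condition`, `run`,
#'   `trial`, `duration_ms`, `correct`, `running_estimate_ms` (the trial
#'   TSV layout).
#' @param gamma,lam Fixed guess and lapse rates for the Weibull fits.
#' @param criterion Accuracy criterion (default 0.80).
#' @param drop_flagged Drop ratio-rule-flagged staircases from the median
#'   (default `TRUE`).
#' @return A list with
#'   `thresholds` (subject_id, condition, threshold_ms, n_runs_used),
#'   `staircases` (per-staircase ratio, flags and per-run threshold), and
#'   `subjects` (per-subject flag counts and exclusion candidacy).
#' @export
estimate_thresholds <- function(trials, gamma = 0.5, lam = 0.04,
                                criterion = 0.80, drop_flagged = TRUE) {
  need <- c("subject_id", "condition", "run", "trial", "duration_ms",
            "correct", "running_estimate_ms")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols)) {
    stop("trial table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  trials <- trials[order(trials$subject_id, trials$condition, trials$run,
                         trials$trial), ]
  key <- interaction(trials$subject_id, trials$condition, trials$run,
                     drop = TRUE)
  pieces <- split(trials, key)
  sc <- do.call(rbind, lapply(pieces, function(d) {
    rec <- staircase_record(d$condition[1], d$duration_ms, d$correct,
                            d$running_estimate_ms)
    qc <- staircase_qc(rec)
    fit <- suppressWarnings(fit_weibull_ml(rec, gamma, lam, criterion))
    data.frame(subject_id = d$subject_id[1], condition = d$condition[1],
               run = d$run[1], threshold_ms = fit$threshold_ms,
               fit_status = fit$status, ratio = qc$ratio,
               flagged = qc$flagged, late_peak = qc$late_peak)
  }))
  rownames(sc) <- NULL
  subj <- do.call(rbind, lapply(split(sc, sc$subject_id), function(d) {
    data.frame(subject_id = d$subject_id[1], n_flagged = sum(d$flagged),
               exclusion_candidate = sum(d$flagged) >= 4)
  }))
  rownames(subj) <- NULL
  thr <- do.call(rbind, lapply(
    split(sc, interaction(sc$subject_id, sc$condition, drop = TRUE)),
    function(d) {
      keep <- if (drop_flagged) !d$flagged else rep(TRUE, nrow(d))
      vals <- d$threshold_ms[keep]
      data.frame(subject_id = d$subject_id[1], condition = d$condition[1],
                 threshold_ms = if (length(vals)) stats::median(vals) else NA_real_,
                 n_runs_used = length(vals))
    }))
  rownames(thr) <- NULL
  list(thresholds = thr, staircases = sc, subjects = subj)
}
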