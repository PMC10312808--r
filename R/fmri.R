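#' Block-design ROI timecourse
#'
#' One run of an ROI-averaged fMRI signal with block onsets, per-TR
#' framewise displacement, and the run's fixation-task hit rate.
#'
#' @param samples Numeric ROI signal, one value per TR.
#' @param onsets Integer block-onset indices (1-based TR index).
#' @param condition Character vector, one label per block
#'   (`"low"`/`"high"` contrast).
#' @param fd_mm Framewise displacement per TR (mm), same length as
#'   `samples`.
#' @param hit_rate Fixation-task hit rate in `[0, 1]`.
#' @param tr_s Repetition time in seconds (default 2).
#' @param block_len_tr Stimulus block length in TRs (default 5, i.e. 10 s).
#' @return An object of class `block_timecourse`.
#' @export
block_timecourse <- function(samples, onsets, condition, fd_mm,
                             hit_rate, tr_s = 2, block_len_tr = 5L) {
  stopifnot(tr_s > 0, length(fd_mm) == length(samples), all(fd_mm >= 0),
            hit_rate >= 0, hit_rate <= 1,
            length(onsets) == length(condition))
  structure(list(samples = samples, onsets = as.integer(onsets),
                 condition = condition, fd_mm = fd_mm, hit_rate = hit_rate,
                 tr_s = tr_s, block_len_tr = as.integer(block_len_tr)),
            class = "block_timecourse")
}

## TR offsets of the peristimulus window: -4 s before onset to 18 s after,
## i.e. 12 samples at TR = 2 s. For other TRs the same time window is
## resampled at the nearest TR.
window_offsets <- function(tr_s) {
  round(seq(-4, 18, by = tr_s) / tr_s)
}

#' Extract one peristimulus block
#'
#' Returns the 12 ROI samples from -4 s before to 18 s after stimulus
#' onset (at TR = 2 s).
#'
#' @param tc A [block_timecourse()].
#' @param onset Block onset (TR index, 1-based).
#' @return Numeric vector of window samples, or `NULL` (with attribute-free
#'   skip semantics handled by the caller) if the window does not fit in
#'   the run; use [extract_block_status()] to obtain an explicit status.
#' @export
extract_block <- function(tc, onset) {
  res <- extract_block_status(tc, onset)
  res$samples
}

#' Extract a block with an explicit status
#'
#' @inheritParams extract_block
#' @return A list with `samples` (numeric or `NULL`) and `status`
#'   (`"ok"` or `"skipped_out_of_range"`).
#' @export
extract_block_status <- function(tc, onset) {
  idx <- onset + window_offsets(tc$tr_s)
  if (min(idx) < 1 || max(idx) > length(tc$samples)) {
    return(list(samples = NULL, status = "skipped_out_of_range"))
  }
  list(samples = tc$samples[idx], status = "ok")
}

#' Percent-signal-change transform of a block
#'
#' Values are expressed relative to the mean of the three pre-onset
#' samples: `(v - baseline) / baseline * 100`.
#'
#' @param block Numeric window from [extract_block()] (pre-onset samples
#'   first; with the default window the first 2 samples precede onset and
#'   the onset sample completes the 3-sample baseline at -4, -2, 0 s).
#' @param n_baseline Number of leading samples forming the baseline
#'   (default 3).
#' @return The block in percent signal change; the baseline samples average
#'   to ~0 by construction.
#' @export
psc_transform <- function(block, n_baseline = 3L) {
  stopifnot(length(block) > n_baseline)
  baseline <- mean(block[seq_len(n_baseline)])
  if (!is.finite(baseline) || baseline <= 0) {
    stop("nonpositive pre-onset baseline; cannot compute percent signal change")
  }
  (block - baseline) / baseline * 100
}

#' Mean response magnitude at 8-12 s
#'
#' Averages the percent-signal-change samples at 8, 10 and 12 s after
#' onset (endpoint-inclusive: 3 samples at TR = 2 s).
#'
#' @param psc_block Percent-signal-change window from [psc_transform()].
#' @param tr_s Repetition time (default 2 s).
#' @return Mean percent signal change over the 8-12 s samples.
#' @export
response_magnitude <- function(psc_block, tr_s = 2) {
  offs <- window_offsets(tr_s)
  sel <- which(offs * tr_s >= 8 & offs * tr_s <= 12)
  stopifnot(length(psc_block) == length(offs))
  mean(psc_block[sel])
}

#' Block-level head-motion exclusion
#'
#' A block is excluded if framewise displacement exceeds 0.9 mm anywhere in
#' the window from 8 TRs before onset up to and including 2 TRs after the
#' block's end (both boundaries inclusive); window portions outside the run
#' are ignored.
#'
#' @param tc A [block_timecourse()].
#' @param onset Block onset (TR index).
#' @param fd_threshold FD threshold in mm (default 0.9).
#' @param pre_tr,post_tr Window margins in TRs (defaults 8 before onset,
#'   2 after block end).
#' @return `"keep"` or `"exclude"`.
#' @export
block_motion_qc <- function(tc, onset, fd_threshold = 0.9, pre_tr = 8L,
                            post_tr = 2L) {
  block_end <- onset + tc$block_len_tr - 1L
  idx <- max(1L, onset - pre_tr):min(length(tc$fd_mm), block_end + post_tr)
  if (any(tc$fd_mm[idx] > fd_threshold)) "exclude" else "keep"
}

#' Run-level exclusion rule
#'
#' A run is excluded when more than one-half of the blocks of either
#' condition are excluded (strictly more: exactly half keeps the run), or
#' the fixation-task hit rate is below 0.60.
#'
#' @param block_status Character vector `"keep"`/`"exclude"`, one per block.
#' @param condition Condition label per block.
#' @param hit_rate Fixation-task hit rate.
#' @return `"keep"` or `"exclude"`.
#' @export
run_qc <- function(block_status, condition, hit_rate) {
  stopifnot(length(block_status) == length(condition))
  if (hit_rate < 0.60) return("exclude")
  for (cond in unique(condition)) {
    sel <- condition == cond
    if (sum(block_status[sel] == "exclude") > sum(sel) / 2) return("exclude")
  }
  "keep"
}

#' Subject-level fMRI response extraction
#'
#' Applies the full block pipeline to a set of runs: window extraction,
#' percent-signal-change transform, 8-12 s response magnitude, block
#' motion QC and run QC, then averages magnitudes over kept blocks of kept
#' runs, per condition.
#'
#' @param runs A list of [block_timecourse()]s for one subject.
#' @return A list with `responses` (data frame: condition,
#'   mean_response_pct, n_blocks_kept) and `runs_kept` (logical per run).
#' @export
extract_subject_responses <- function(runs) {
  per_block <- list()
  runs_kept <- logical(length(runs))
  for (ri in seq_along(runs)) {
    tc <- runs[[ri]]
    status <- character(length(tc$onsets))
    mag <- numeric(length(tc$onsets))
    for (bi in seq_along(tc$onsets)) {
      ext <- extract_block_status(tc, tc$onsets[bi])
      if (ext$status != "ok") {
        status[bi] <- "exclude"; mag[bi] <- NA_real_; next
      }
      status[bi] <- block_motion_qc(tc, tc$onsets[bi])
      mag[bi] <- response_magnitude(psc_transform(ext$samples), tc$tr_s)
    }
    runs_kept[ri] <- run_qc(status, tc$condition, tc$hit_rate) == "keep"
    if (runs_kept[ri]) {
      per_block[[length(per_block) + 1L]] <- data.frame(
        condition = tc$condition, status = status, magnitude = mag)
    }
  }
  if (!length(per_block)) {
    return(list(responses = data.frame(condition = character(0),
                                       mean_response_pct = numeric(0),
                                       n_blocks_kept = integer(0)),
                runs_kept = runs_kept))
  }
  blocks <- do.call(rbind, per_block)
  kept <- blocks[blocks$status == "keep", ]
  resp <- do.call(rbind, lapply(split(kept, kept$condition), function(d) {
    data.frame(condition = d$condition[1],
               mean_response_pct = mean(d$magnitude),
               n_blocks_kept = nrow(d))
  }))
  rownames(resp) <- NULL
  list(responses = resp, runs_kept = runs_kept)
}
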