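#' Run configuration
#'
#' Describes one end-to-end analysis: where data come from (a synthetic
#' preset or user-supplied TSV paths), screening options, the split
#' fraction, region definitions, and output location. Exactly one of
#' `simulate` / `inputs` must be given.
#'
#' @param simulate `NULL`, or a list with `preset` (see [simulate_study()]),
#'   `seed`, optional `n` and further [cohort_config()] overrides.
#' @param inputs `NULL`, or a list of file paths: `trials` (trial TSV),
#'   `parcels` (parcel TSV), optionally `parcels_dialect`, `timecourses`
#'   and `blocks` (fMRI TSVs).
#' @param model Model parameters ([default_model_params()]) used for
#'   model-pattern comparison.
#' @param alpha Screening alpha (default 0.01).
#' @param sign Screening sign filter (default `"negative"`).
#' @param behavior_conditions Condition labels averaged into the screening
#'   behavior (default the two smallest high-contrast conditions).
#' @param use_raw Screen on raw rather than normalized surface area
#'   (default `FALSE`).
#' @param split_fraction Group-split fraction (default `1/3`).
#' @param regions Region definitions (default [default_regions()]).
#' @param outdir Optional output directory for TSV/JSON reports.
#' @return An object of class `run_config`.
#' @export
run_config <- function(simulate = NULL, inputs = NULL,
                       model = default_model_params(), alpha = 0.01,
                       sign = "negative",
                       behavior_conditions = c("size0.5_c0.98", "size1_c0.98"),
                       use_raw = FALSE, split_fraction = 1/3,
                       regions = default_regions(), outdir = NULL) {
  if (is.null(simulate) == is.null(inputs)) {
    stop("exactly one of `simulate` / `inputs` must be given")
  }
  if (!length(regions)) stop("regions must be nonempty")
  structure(list(simulate = simulate, inputs = inputs, model = model,
                 alpha = alpha, sign = sign,
                 behavior_conditions = behavior_conditions,
                 use_raw = use_raw, split_fraction = split_fraction,
                 regions = regions, outdir = outdir),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path Path to a JSON file; keys mirror [run_config()] arguments
#'   (the `model` block mirrors [model_params()] fields; `regions` is a
#'   named list of `{hemi: [...], parcel: [...]}` objects).
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  model <- if (is.null(j$model)) default_model_params()
           else do.call(default_model_params, as.list(j$model))
  regions <- if (is.null(j$regions)) default_regions()
             else lapply(stats::setNames(names(j$regions), names(j$regions)),
                         function(nm) region_def(nm, j$regions[[nm]]$hemi,
                                                 j$regions[[nm]]$parcel))
  args <- j[setdiff(names(j), c("model", "regions"))]
  do.call(run_config, c(args, list(model = model, regions = regions)))
}

## Resolve a config's data source into in-memory objects.
pipeline_inputs <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim <- do.call(simulate_study, cfg$simulate)
    list(trials = sim$trials, parcels = sim$parcels,
         fmri_runs = sim$fmri_runs, truth = sim$truth, preset = sim$preset)
  } else {
    ins <- cfg$inputs
    dialect <- if (is.null(ins$parcels_dialect)) "tsv" else ins$parcels_dialect
    out <- list(
      trials = if (!is.null(ins$trials))
        utils::read.delim(ins$trials, sep = "\t") else NULL,
      parcels = if (!is.null(ins$parcels))
        read_parcel_table(ins$parcels, dialect) else NULL,
      preset = NULL)
    if (!is.null(ins$timecourses)) {
      out$fmri_runs <- read_fmri_tables(ins$timecourses, ins$blocks)
    }
    out
  }
}

#' Read fMRI timecourse and block tables
#'
#' @param timecourse_path TSV with columns `subject_id`, `run`, `tr_index`,
#'   `signal`, `fd_mm`.
#' @param blocks_path TSV with columns `subject_id`, `run`, `onset_index`,
#'   `condition`, `hit_rate` (run-level, repeated per block).
#' @param tr_s Repetition time (default 2 s).
#' @return Per-subject lists of [block_timecourse()]s.
#' @export
read_fmri_tables <- function(timecourse_path, blocks_path, tr_s = 2) {
  tc <- utils::read.delim(timecourse_path, sep = "\t")
  bl <- utils::read.delim(blocks_path, sep = "\t")
  stopifnot(all(c("subject_id", "run", "tr_index", "signal", "fd_mm") %in% names(tc)),
            all(c("subject_id", "run", "onset_index", "condition", "hit_rate") %in% names(bl)))
  out <- lapply(split(tc, tc$subject_id), function(ts) {
    lapply(split(ts, ts$run), function(tr) {
      tr <- tr[order(tr$tr_index), ]
      b <- bl[bl$subject_id == tr$subject_id[1] & bl$run == tr$run[1], ]
      block_timecourse(tr$signal, b$onset_index, b$condition, tr$fd_mm,
                       hit_rate = b$hit_rate[1], tr_s = tr_s)
    })
  })
  out
}

## Wide subject x condition threshold matrix from estimate_thresholds output.
thresholds_wide <- function(thr) {
  conds <- sort(unique(thr$condition))
  ids <- sort(unique(thr$subject_id))
  m <- matrix(NA_real_, length(ids), length(conds),
              dimnames = list(ids, conds))
  m[cbind(match(thr$subject_id, ids), match(thr$condition, conds))] <-
    thr$threshold_ms
  m
}

subset_parcels <- function(parcels, subjects) {
  kind <- attr(parcels, "kind")
  parcel_table(as.data.frame(parcels)[parcels$subject_id %in% subjects, ],
               kind)
}

region_correlations <- function(sa_by_region, measures) {
  rows <- list()
  for (rg in names(sa_by_region)) {
    sa <- sa_by_region[[rg]]
    for (m in colnames(measures)) {
      pr <- pearson_r(sa[rownames(measures)], measures[, m])
      rows[[length(rows) + 1L]] <- data.frame(
        region = rg, measure = m, r = pr$r, p = pr$p, n = pr$n)
    }
  }
  do.call(rbind, rows)
}

#' Run the primary surface-area / threshold analysis
#'
#' Full pipeline for the main experiment design: per-staircase Weibull
#' thresholds, staircase and subject QC, surface-area normalization,
#' parcel-wise screening against the behavioral measure (mean of the two
#' smallest high-contrast conditions by default), region-sum correlations
#' (including parietal/frontal against the small/large low-contrast
#' conditions), and third-split group threshold profiles per region.
#'
#' @param cfg A [run_config()].
#' @return A report list (also written as JSON + TSVs when `cfg$outdir` is
#'   set): sample counts, QC summary, screen table, region tests, group
#'   splits, and group-mean threshold profiles.
#' @export
run_exp1 <- function(cfg) {
  dat <- pipeline_inputs(cfg)
  est <- estimate_thresholds(dat$trials)
  excl <- est$subjects$subject_id[est$subjects$exclusion_candidate]
  keep <- setdiff(unique(est$thresholds$subject_id), excl)
  log_stage("thresholds", sprintf(
    "%d subjects in, %d excluded (>=4 flagged staircases), %d staircases flagged",
    nrow(est$subjects), length(excl), sum(est$staircases$flagged)))
  if (length(keep) < 10) stop("fewer than 10 surviving subjects; aborting")
  wide <- thresholds_wide(est$thresholds[est$thresholds$subject_id %in% keep, ])
  bc <- cfg$behavior_conditions
  if (!all(bc %in% colnames(wide))) {
    stop("behavior conditions missing from threshold table: ",
         paste(setdiff(bc, colnames(wide)), collapse = ", "))
  }
  behavior <- rowMeans(wide[, bc, drop = FALSE])
  parcels <- subset_parcels(dat$parcels, keep)
  sa <- if (cfg$use_raw) parcels else normalize_sa(parcels)
  screen <- parcel_screen(sa, behavior, alpha = cfg$alpha, sign = cfg$sign)
  log_stage("screen", sprintf("%d of %d parcels selected at alpha %g",
                              sum(screen$selected), nrow(screen), cfg$alpha))
  sa_by_region <- lapply(cfg$regions, function(rg) region_sum(sa, rg))
  measures <- cbind(behavior = behavior,
                    wide[, intersect(c("size0.5_c0.03", "size6_c0.03"),
                                     colnames(wide)), drop = FALSE])
  region_tests <- region_correlations(sa_by_region, measures)
  splits <- lapply(sa_by_region, function(v) group_split(v, cfg$split_fraction))
  profiles <- lapply(splits, function(gs) {
    small <- names(gs)[gs == "small"]; large <- names(gs)[gs == "large"]
    data.frame(condition = colnames(wide),
               small_sa_mean = colMeans(wide[small, , drop = FALSE], na.rm = TRUE),
               large_sa_mean = colMeans(wide[large, , drop = FALSE], na.rm = TRUE),
               row.names = NULL)
  })
  report <- list(
    experiment = "exp1",
    n_subjects_in = nrow(est$subjects), n_excluded = length(excl),
    n_subjects = length(keep), excluded = excl,
    qc = list(n_staircases = nrow(est$staircases),
              n_flagged = sum(est$staircases$flagged)),
    behavior_conditions = bc, behavior = as.list(behavior),
    screen = screen, region_tests = region_tests,
    splits = lapply(splits, function(s) as.list(stats::setNames(as.character(s), names(s)))),
    profiles = profiles,
    thresholds = est$thresholds, staircases = est$staircases)
  maybe_write_report(report, cfg$outdir,
                     tsv = list(thresholds = est$thresholds,
                                staircases = est$staircases,
                                screen = screen,
                                region_tests = region_tests))
  invisible(report)
}

#' Run the center-surround (gap) analysis
#'
#' Thresholds per gap condition, per-subject small-gap and large-gap
#' averages, half-split group profiles by region, and region-sum
#' correlations with the two gap averages.
#'
#' @param cfg A [run_config()] whose data carry the five gap conditions.
#' @return A report list (written when `cfg$outdir` is set).
#' @export
run_exp2 <- function(cfg) {
  dat <- pipeline_inputs(cfg)
  est <- estimate_thresholds(dat$trials)
  excl <- est$subjects$subject_id[est$subjects$exclusion_candidate]
  keep <- setdiff(unique(est$thresholds$subject_id), excl)
  if (length(keep) < 10) stop("fewer than 10 surviving subjects; aborting")
  wide <- thresholds_wide(est$thresholds[est$thresholds$subject_id %in% keep, ])
  gaps <- c(0.5, 1, 1.5, 2.5, 4.5)
  need <- gap_label(gaps)
  missing_conds <- setdiff(need, colnames(wide))
  if (length(missing_conds)) {
    stop("missing gap condition(s): ", paste(missing_conds, collapse = ", "))
  }
  ga <- t(apply(wide[, need], 1, function(v) {
    unlist(gap_average(stats::setNames(v, gaps)))
  }))
  parcels <- subset_parcels(dat$parcels, keep)
  sa <- if (cfg$use_raw) parcels else normalize_sa(parcels)
  sa_by_region <- lapply(cfg$regions, function(rg) region_sum(sa, rg))
  region_tests <- region_correlations(sa_by_region, ga)
  splits <- lapply(sa_by_region, function(v) group_split(v, 1/2))
  profiles <- lapply(splits, function(gs) {
    small <- names(gs)[gs == "small"]; large <- names(gs)[gs == "large"]
    data.frame(condition = colnames(wide),
               small_sa_mean = colMeans(wide[small, , drop = FALSE], na.rm = TRUE),
               large_sa_mean = colMeans(wide[large, , drop = FALSE], na.rm = TRUE),
               row.names = NULL)
  })
  report <- list(
    experiment = "exp2",
    n_subjects_in = nrow(est$subjects), n_excluded = length(excl),
    n_subjects = length(keep),
    gap_averages = data.frame(subject_id = rownames(ga),
                              small_gap_mean = ga[, "small_gap_mean"],
                              large_gap_mean = ga[, "large_gap_mean"],
                              row.names = NULL),
    region_tests = region_tests, profiles = profiles,
    thresholds = est$thresholds)
  maybe_write_report(report, cfg$outdir,
                     tsv = list(thresholds = est$thresholds,
                                region_tests = region_tests,
                                gap_averages = report$gap_averages))
  invisible(report)
}

#' Compare observed group-split profiles against model manipulations
#'
#' Computes the model's predicted per-condition threshold difference under
#' (a) widening the excitatory drive (3 -> 4.5 a.u.) and (b) widening the
#' top-down gain (3 -> 7 a.u.), then scores each observed group split
#' (small-SA minus large-SA mean threshold per condition) against each
#' prediction by sign concordance. Differences smaller than `floor_ms` are
#' ignored; the winning parameter per split is the one agreeing on more
#' conditions, with ties declared inconclusive. The score is a qualitative
#' stand-in for a visual pattern comparison, not a fit statistic.
#'
#' @param profiles Named list of data frames with columns `condition`,
#'   `small_sa_mean`, `large_sa_mean` (from [run_exp1()]).
#' @param params Base [model_params()].
#' @param floor_ms Minimum absolute difference considered informative
#'   (default 2 ms).
#' @return A data frame: split, score_excit, score_attn, n_informative,
#'   winner (`"excit_width"`, `"attn_width"`, or `"inconclusive"`).
#' @export
run_model_comparison <- function(profiles, params = default_model_params(),
                                 floor_ms = 2) {
  base_args <- unclass(params)
  pred_for <- function(ew, aw) {
    p <- do.call(model_params, utils::modifyList(base_args,
      list(excit_width = ew, attn_width = aw)))
    tab <- predict_condition_grid(p)
    stats::setNames(tab$predicted_ms, condition_label(tab$size_deg, tab$contrast))
  }
  pred_e <- pred_for(4.5, params$attn_width) - pred_for(3, params$attn_width)
  pred_a <- pred_for(params$excit_width, 7) - pred_for(params$excit_width, 3)
  rows <- lapply(names(profiles), function(nm) {
    pf <- profiles[[nm]]
    conds <- intersect(pf$condition, names(pred_e))
    obs <- stats::setNames(pf$small_sa_mean - pf$large_sa_mean, pf$condition)[conds]
    ## a condition is informative for a prediction only when both the
    ## observed and the predicted difference clear the floor; sign
    ## agreement on informative conditions is the score
    score <- function(pred) {
      use <- abs(obs) >= floor_ms & abs(pred[conds]) >= floor_ms
      sum(sign(obs[use]) == sign(pred[conds][use]))
    }
    n_inf <- sum(abs(obs) >= floor_ms)
    se <- score(pred_e); sa_ <- score(pred_a)
    winner <- if (n_inf == 0 || se == sa_) "inconclusive"
              else if (se > sa_) "excit_width" else "attn_width"
    data.frame(split = nm, score_excit = se, score_attn = sa_,
               n_informative = n_inf, winner = winner)
  })
  out <- do.call(rbind, rows)
  attr(out, "predictions") <- list(excit_width = pred_e, attn_width = pred_a)
  out
}

#' Run the fMRI responsiveness analysis
#'
#' Extracts per-subject hMT+ response magnitudes (percent signal change,
#' 8-12 s window, motion- and performance-QC applied) and correlates them
#' with frontal and parietal normalized region surface area.
#'
#' @param cfg A [run_config()] whose data include ROI timecourses.
#' @return A report list (written when `cfg$outdir` is set).
#' @export
run_exp4 <- function(cfg) {
  dat <- pipeline_inputs(cfg)
  if (is.null(dat$fmri_runs)) stop("no fMRI timecourses in inputs")
  resp <- lapply(dat$fmri_runs, extract_subject_responses)
  rows <- do.call(rbind, lapply(names(resp), function(id) {
    r <- resp[[id]]$responses
    if (!nrow(r)) return(NULL)
    data.frame(subject_id = id, r)
  }))
  if (is.null(rows) || !nrow(rows)) stop("all fMRI runs excluded by QC; aborting")
  log_stage("fmri", sprintf("%d of %d subjects retain usable runs",
                            length(unique(rows$subject_id)), length(resp)))
  ## subject-level responsiveness: mean over condition means
  subj <- vapply(split(rows, rows$subject_id),
                 function(d) mean(d$mean_response_pct), numeric(1))
  parcels <- subset_parcels(dat$parcels, names(subj))
  sa <- if (cfg$use_raw) parcels else normalize_sa(parcels)
  sa_by_region <- lapply(cfg$regions, function(rg) region_sum(sa, rg))
  measures <- cbind(hmt_response = subj)
  region_tests <- region_correlations(sa_by_region, measures)
  report <- list(experiment = "exp4", n_subjects = length(subj),
                 responses = rows, subject_response = as.list(subj),
                 region_tests = region_tests)
  maybe_write_report(report, cfg$outdir,
                     tsv = list(responses = rows, region_tests = region_tests))
  invisible(report)
}

log_stage <- function(stage, msg) {
  message(sprintf("[normgain:%s] %s", stage, msg))
}

maybe_write_report <- function(report, outdir, tsv = list()) {
  if (is.null(outdir)) return(invisible(NULL))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  for (nm in names(tsv)) {
    utils::write.table(tsv[[nm]], file.path(outdir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
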