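#' Synthetic-cohort configuration
#'
#' Parameters of the generative model for a synthetic study: parcel
#' surface-area tables, subject-specific normalization-model parameters
#' linked to regional surface area, trial-level staircase behavior
#' (including a minority of inattentive "rising-staircase" observers), and
#' block-design ROI timecourses linked to frontal surface area.
#'
#' Linkage slopes are expressed in parameter units per cohort standard
#' deviation of the (normalized) region share, negated: subjects with
#' larger parietal share get narrower excitatory drive, subjects with
#' larger frontal share get narrower top-down gain. Defaults were chosen
#' once so that the injected cohort correlations between region share and
#' behavior approximate the reported magnitudes (about -0.45 parietal,
#' -0.40 frontal); see the methods vignette.
#'
#' @param n_subjects Cohort size (default 62).
#' @param n_parcels_per_hemi Parcels per hemisphere (default 180).
#' @param seed Integer seed; required, all generation is deterministic
#'   given it.
#' @param parcel_sd Lognormal sd of parcel share weights (default 0.4;
#'   keeps typical shares in the 0.5-1.5% band).
#' @param hemi_total_mean Mean hemisphere surface area, mm^2 (default 9e4).
#' @param hemi_total_sd Lognormal sd of hemisphere totals (default 0.08).
#' @param slope_e Excitatory-width linkage slope (sigma_e units per SD of
#'   parietal share; default 0.6, clipped to `[3, 4.5]`).
#' @param slope_a Attention-width linkage slope (sigma_a units per SD of
#'   frontal share; default 1.8, clipped to `[3, 7]`).
#' @param threshold_noise_sd Lognormal sd of multiplicative subject noise
#'   on true thresholds (default 0.05).
#' @param beta_sd Lognormal sd of observer psychometric slopes around 3
#'   (default 0.15).
#' @param bad_fraction Fraction of inattentive observers whose staircases
#'   rise late (default 11/73).
#' @param bad_staircase_prob Probability that any given staircase of an
#'   inattentive observer contains a late guessing segment (default 0.4,
#'   giving roughly 8-10 affected staircases of 24 -- comfortably past the
#'   4-flag exclusion rule while keeping the per-subject flag count in a
#'   realistic range).
#' @param n_runs Staircase runs per condition (default 4).
#' @param n_trials Trials per staircase (default 25).
#' @param fmri_base Baseline hMT+ high-contrast response amplitude, percent
#'   signal change (default 0.8).
#' @param fmri_slope Amplitude increase per SD of frontal share
#'   (default 0.25).
#' @param fmri_amp_sd SD of subject-level amplitude noise (default 0.25).
#' @param fmri_tr_noise SD of additive per-TR signal noise, in raw signal
#'   units on a baseline of 100 (default 0.15).
#' @param model Non-manipulated model parameters
#'   ([default_model_params()]).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 62L, n_parcels_per_hemi = 180L,
                          seed, parcel_sd = 0.4, hemi_total_mean = 9e4,
                          hemi_total_sd = 0.08, slope_e = 0.6, slope_a = 1.8,
                          threshold_noise_sd = 0.05, beta_sd = 0.15,
                          bad_fraction = 11 / 73, bad_staircase_prob = 0.4,
                          n_runs = 4L, n_trials = 25L,
                          fmri_base = 0.8, fmri_slope = 0.25,
                          fmri_amp_sd = 0.25, fmri_tr_noise = 0.15,
                          model = default_model_params()) {
  if (missing(seed) || is.null(seed)) stop("cohort_config requires a seed")
  stopifnot(n_subjects >= 8, n_parcels_per_hemi >= 6, parcel_sd >= 0,
            threshold_noise_sd >= 0, beta_sd >= 0,
            bad_fraction >= 0, bad_fraction < 1)
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_parcels_per_hemi = as.integer(n_parcels_per_hemi),
    seed = as.integer(seed), parcel_sd = parcel_sd,
    hemi_total_mean = hemi_total_mean, hemi_total_sd = hemi_total_sd,
    slope_e = slope_e, slope_a = slope_a,
    threshold_noise_sd = threshold_noise_sd, beta_sd = beta_sd,
    bad_fraction = bad_fraction, bad_staircase_prob = bad_staircase_prob,
    n_runs = as.integer(n_runs),
    n_trials = as.integer(n_trials), fmri_base = fmri_base,
    fmri_slope = fmri_slope, fmri_amp_sd = fmri_amp_sd,
    fmri_tr_noise = fmri_tr_noise, model = model), class = "cohort_config")
}

cohort_parcel_names <- function(n) {
  named <- c("7AL", "VIP", "LIPd", "IP1", "IP2", "11l")
  c(named, sprintf("P%03d", seq_len(n - length(named))))
}

#' Generate raw parcel surface-area tables
#'
#' Per subject and hemisphere, parcel shares are drawn lognormal and
#' renormalized to sum to 1 (typical share ~0.55%, within the 0.5-1.5%
#' band); hemisphere totals are lognormal around 9e4 mm^2; raw values are
#' share x total. The atlas's six analysis parcels (7AL, VIP, LIPd, IP1,
#' IP2, 11l) are present in both hemispheres; remaining parcels carry
#' synthetic names.
#'
#' @param cfg A [cohort_config()].
#' @return A list with `parcels` (raw [parcel_table()]) and `shares`
#'   (data frame subject_id, hemi, parcel, share).
#' @export
generate_parcels <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$seed)
  np <- cfg$n_parcels_per_hemi
  ids <- sprintf("S%03d", seq_len(cfg$n_subjects))
  pnames <- cohort_parcel_names(np)
  rows <- vector("list", cfg$n_subjects * 2L)
  k <- 0L
  for (s in ids) {
    for (h in c("LH", "RH")) {
      w <- stats::rlnorm(np, meanlog = 0, sdlog = cfg$parcel_sd)
      share <- w / sum(w)
      total <- stats::rlnorm(1, log(cfg$hemi_total_mean), cfg$hemi_total_sd)
      k <- k + 1L
      rows[[k]] <- data.frame(subject_id = s, hemi = h, parcel = pnames,
                              share = share, value = share * total)
    }
  }
  long <- do.call(rbind, rows)
  list(parcels = parcel_table(long[, c("subject_id", "hemi", "parcel", "value")],
                              "raw"),
       shares = long[, c("subject_id", "hemi", "parcel", "share")])
}

#' Link region shares to model parameters
#'
#' Affine-decreasing maps from normalized region share (z-scored within the
#' cohort) to the subject's excitatory width (clipped to `[3, 4.5]`) and
#' attention width (clipped to `[3, 7]`). Zero slopes put every subject at
#' the midpoint.
#'
#' @param parcels Raw [parcel_table()] from [generate_parcels()].
#' @param cfg A [cohort_config()].
#' @param regions Region definitions (default [default_regions()]).
#' @return A data frame `truth`: subject_id, parietal_share, frontal_share,
#'   sigma_e, sigma_a.
#' @export
link_parameters <- function(parcels, cfg, regions = default_regions()) {
  norm <- normalize_sa(parcels)
  par_share <- region_sum(norm, regions$parietal)
  fro_share <- region_sum(norm, regions$frontal)
  zp <- if (stats::sd(par_share) > 0) as.vector(scale(par_share)) else par_share * 0
  zf <- if (stats::sd(fro_share) > 0) as.vector(scale(fro_share)) else fro_share * 0
  data.frame(
    subject_id = names(par_share),
    parietal_share = as.numeric(par_share),
    frontal_share = as.numeric(fro_share),
    sigma_e = pmin(4.5, pmax(3, 3.75 - cfg$slope_e * zp)),
    sigma_a = pmin(7, pmax(3, 5 - cfg$slope_a * zf)))
}

#' Generate per-condition true thresholds from the normalization model
#'
#' Runs the model once per subject with that subject's excitatory and
#' attention widths and multiplies each condition's predicted threshold by
#' seeded lognormal subject noise.
#'
#' @param truth Data frame from [link_parameters()].
#' @param cfg A [cohort_config()].
#' @param sizes_deg,contrasts Condition grid (defaults
#'   [default_sizes_deg()], [default_contrasts()]).
#' @param gaps_deg Optional gap sizes; when non-`NULL`, gap conditions from
#'   [predict_gap_grid()] are appended.
#' @return Data frame subject_id, condition, true_ms.
#' @export
generate_true_thresholds <- function(truth, cfg,
                                     sizes_deg = default_sizes_deg(),
                                     contrasts = default_contrasts(),
                                     gaps_deg = NULL) {
  set.seed(cfg$seed + 1L)
  out <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    p <- default_model_params(excit_width = truth$sigma_e[i],
                              attn_width = truth$sigma_a[i])
    for (nm in setdiff(names(cfg$model), c("excit_width", "attn_width"))) {
      p[[nm]] <- cfg$model[[nm]]
    }
    cond <- character(0); ms <- numeric(0)
    if (length(sizes_deg)) {
      tab <- predict_condition_grid(p, sizes_deg, contrasts)
      cond <- condition_label(tab$size_deg, tab$contrast)
      ms <- tab$predicted_ms
    }
    if (!is.null(gaps_deg)) {
      gtab <- predict_gap_grid(p, gaps_deg)
      cond <- c(cond, gap_label(gtab$gap_deg))
      ms <- c(ms, gtab$predicted_ms)
    }
    noise <- exp(stats::rnorm(length(ms), 0, cfg$threshold_noise_sd))
    out[[i]] <- data.frame(subject_id = truth$subject_id[i],
                           condition = cond, true_ms = ms * noise)
  }
  do.call(rbind, out)
}

#' Condition label helpers
#'
#' @param size_deg,contrast Size (radius, deg) and contrast.
#' @return Character label(s), e.g. `"size0.5_c0.98"`.
#' @export
condition_label <- function(size_deg, contrast) {
  sprintf("size%g_c%g", size_deg, contrast)
}

#' @rdname condition_label
#' @param gap_deg Gap size (deg).
#' @export
gap_label <- function(gap_deg) sprintf("gap%g", gap_deg)

#' Simulate trial-level staircase behavior for a cohort
#'
#' For every subject x condition x run, simulates a 25-trial Psi staircase
#' against an observer whose criterion-accuracy duration equals the
#' subject's true threshold (slope lognormal around 3). Inattentive ("bad")
#' observers guess at p = 0.5 from a random late trial onward in every
#' staircase, producing the rising-staircase phenotype targeted by QC.
#'
#' @param truth Data frame from [link_parameters()] (adds column `good`).
#' @param true_thresholds Data frame from [generate_true_thresholds()].
#' @param cfg A [cohort_config()].
#' @return A list with `trials` (trial TSV layout: subject_id, condition,
#'   run, trial, duration_ms, correct, running_estimate_ms) and `truth`
#'   (input truth with `good` and `beta` columns).
#' @export
simulate_trials <- function(truth, true_thresholds, cfg) {
  set.seed(cfg$seed + 2L)
  n <- nrow(truth)
  n_bad <- round(cfg$bad_fraction * n)
  good <- rep(TRUE, n)
  if (n_bad > 0) good[sample.int(n, n_bad)] <- FALSE
  truth$good <- good
  truth$beta <- stats::rlnorm(n, log(3), cfg$beta_sd)
  des <- merge(true_thresholds,
               truth[, c("subject_id", "good", "beta")], by = "subject_id")
  des <- des[rep(seq_len(nrow(des)), each = cfg$n_runs), ]
  des$run <- rep(seq_len(cfg$n_runs), length.out = nrow(des))
  des <- des[order(des$subject_id, des$condition, des$run), ]
  ## clamp targets into the lattice so observers are estimable
  tgt <- pmin(pmax(des$true_ms, 8), 300)
  alpha <- vapply(seq_len(nrow(des)), function(i) {
    observer_from_threshold(tgt[i], des$beta[i])$alpha
  }, numeric(1))
  guess <- lapply(seq_len(nrow(des)), function(i) {
    if (des$good[i] || stats::runif(1) > cfg$bad_staircase_prob) integer(0)
    else seq.int(sample(12:18, 1), cfg$n_trials)
  })
  res <- run_staircases_batch(alpha = alpha, beta = des$beta,
                              n_trials = cfg$n_trials, guess_trials = guess)
  S <- nrow(des)
  trials <- data.frame(
    subject_id = rep(des$subject_id, each = cfg$n_trials),
    condition = rep(des$condition, each = cfg$n_trials),
    run = rep(des$run, each = cfg$n_trials),
    trial = rep(seq_len(cfg$n_trials), times = S),
    duration_ms = as.vector(res$duration),
    correct = as.vector(res$correct),
    running_estimate_ms = as.vector(res$estimate))
  list(trials = trials, truth = truth)
}

## Canonical double-gamma HRF sampled at TR resolution, scaled so that the
## 8-12 s window mean of an isolated 10 s block response is 1.
hrf_kernel <- function(tr_s = 2, duration_s = 30) {
  t <- seq(0, duration_s, by = tr_s)
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h
}

block_response_shape <- function(tr_s = 2, block_len_tr = 5L) {
  h <- hrf_kernel(tr_s)
  box <- rep(1, block_len_tr)
  r <- stats::convolve(box, rev(h), type = "open")
  t <- (seq_along(r) - 1) * tr_s           # time since block onset
  r / mean(r[t >= 8 & t <= 12])
}

#' Simulate block-design ROI timecourses for a cohort
#'
#' Each run alternates 13 blank and 12 stimulus blocks (6 low, 6 high
#' contrast, 10 s each). The noiseless response is a boxcar convolved with
#' a canonical double-gamma kernel, with subject amplitude affine-increasing
#' in frontal share (plus amplitude noise), low-contrast blocks at half the
#' high-contrast amplitude, additive per-TR noise, occasional framewise-
#' displacement spikes (> 0.9 mm) and occasional low fixation hit rates so
#' the exclusion rules are exercised.
#'
#' @param truth Data frame from [link_parameters()].
#' @param cfg A [cohort_config()].
#' @param n_runs_fmri Runs per subject (default 3).
#' @param spike_run_prob Probability a run carries FD spikes (default 0.2).
#' @param low_hit_prob Probability a run has a sub-0.6 hit rate
#'   (default 0.05).
#' @return A list with `runs` (per subject, a list of
#'   [block_timecourse()]s), and `truth` with the injected `hmt_amp`.
#' @export
simulate_fmri <- function(truth, cfg, n_runs_fmri = 3L, spike_run_prob = 0.2,
                          low_hit_prob = 0.05) {
  set.seed(cfg$seed + 3L)
  zf <- if (stats::sd(truth$frontal_share) > 0)
    as.vector(scale(truth$frontal_share)) else truth$frontal_share * 0
  amp <- pmax(0.1, cfg$fmri_base + cfg$fmri_slope * zf +
                stats::rnorm(nrow(truth), 0, cfg$fmri_amp_sd))
  truth$hmt_amp <- amp
  shape <- block_response_shape()
  blk <- 5L                                 # 10 s blocks at TR = 2 s
  n_blocks <- 25L                           # B S B S ... B
  n_tr <- n_blocks * blk
  runs <- vector("list", nrow(truth))
  names(runs) <- truth$subject_id
  for (i in seq_len(nrow(truth))) {
    subj_runs <- vector("list", n_runs_fmri)
    for (r in seq_len(n_runs_fmri)) {
      onsets <- as.integer(seq(2, 24, by = 2) - 1) * blk + 1L  # stim blocks
      condition <- rep(c("low", "high"), length.out = length(onsets))
      signal <- rep(0, n_tr)
      for (b in seq_along(onsets)) {
        a <- amp[i] * if (condition[b] == "high") 1 else 0.5
        seg <- onsets[b]:min(n_tr, onsets[b] + length(shape) - 1L)
        signal[seg] <- signal[seg] + a * shape[seq_along(seg)]
      }
      raw <- 100 * (1 + signal / 100) + stats::rnorm(n_tr, 0, cfg$fmri_tr_noise)
      fd <- abs(stats::rnorm(n_tr, 0.08, 0.05))
      if (stats::runif(1) < spike_run_prob) {
        fd[sample.int(n_tr, 2)] <- stats::runif(2, 1.0, 2.0)
      }
      hit <- if (stats::runif(1) < low_hit_prob) stats::runif(1, 0.3, 0.55)
             else stats::runif(1, 0.7, 1.0)
      subj_runs[[r]] <- block_timecourse(raw, onsets, condition, fd, hit,
                                         tr_s = 2, block_len_tr = blk)
    }
    runs[[i]] <- subj_runs
  }
  list(runs = runs, truth = truth)
}

#' Generate a full synthetic study
#'
#' One call produces everything a pipeline run needs, deterministically
#' from the seed. Presets: `"exp1"` (62 subjects, 3 sizes x 2 contrasts),
#' `"exp2"` (29 subjects, 5 gap conditions), `"exp3"` (20 subjects, exp1
#' design), `"exp4"` (30 subjects, exp1 behavior plus fMRI runs), and
#' `"null"` (exp1 design with zero linkage slopes and no inattentive
#' observers).
#'
#' @param preset One of `"exp1"`, `"exp2"`, `"exp3"`, `"exp4"`, `"null"`.
#' @param seed Integer seed.
#' @param n Optional cohort-size override.
#' @param ... Further [cohort_config()] overrides.
#' @return A list with `config`, `parcels` (raw [parcel_table()]), `truth`,
#'   `trials`, and (exp4) `fmri_runs`.
#' @export
simulate_study <- function(preset = c("exp1", "exp2", "exp3", "exp4", "null"),
                           seed, n = NULL, ...) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    exp1 = list(n_subjects = 62L),
    exp2 = list(n_subjects = 29L),
    exp3 = list(n_subjects = 20L),
    exp4 = list(n_subjects = 30L),
    null = list(n_subjects = 62L, slope_e = 0, slope_a = 0,
                fmri_slope = 0, bad_fraction = 0))
  over <- list(...)
  if (!is.null(n)) defaults$n_subjects <- as.integer(n)
  defaults[names(over)] <- over
  cfg <- do.call(cohort_config, c(defaults, list(seed = seed)))
  gen <- generate_parcels(cfg)
  truth <- link_parameters(gen$parcels, cfg)
  if (preset == "exp2") {
    thr <- generate_true_thresholds(truth, cfg, sizes_deg = numeric(0),
                                    gaps_deg = c(0.5, 1, 1.5, 2.5, 4.5))
  } else {
    thr <- generate_true_thresholds(truth, cfg)
  }
  sim <- simulate_trials(truth, thr, cfg)
  out <- list(config = cfg, preset = preset, parcels = gen$parcels,
              shares = gen$shares, truth = sim$truth,
              true_thresholds = thr, trials = sim$trials)
  if (preset == "exp4") {
    fm <- simulate_fmri(sim$truth, cfg)
    out$fmri_runs <- fm$runs
    out$truth <- fm$truth
  }
  out
}
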