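small_cfg <- function(seed = 5, ...) {
  cohort_config(n_subjects = 12L, n_parcels_per_hemi = 20L, seed = seed, ...)
}

test_that("parcel generation: determinism, closure, share band", {
  cfg <- small_cfg()
  g1 <- generate_parcels(cfg)
  g2 <- generate_parcels(cfg)
  expect_identical(g1, g2)

  norm <- normalize_sa(g1$parcels)
  key <- interaction(norm$subject_id, norm$hemi)
  expect_true(all(abs(tapply(norm$value, key, sum) - 100) < 1e-6))

  ## with 180 parcels the typical share sits in the 0.5-1.5% band
  big <- generate_parcels(cohort_config(n_subjects = 8L, seed = 6))
  med <- median(big$shares$share)
  expect_gt(med, 0.005 * 0.8)
  expect_lt(med, 0.015 * 1.2)
  ## raw values scale around the 9e4 mm^2 hemisphere total
  tot <- tapply(big$parcels$value,
                interaction(big$parcels$subject_id, big$parcels$hemi), sum)
  expect_gt(min(tot), 9e4 * 0.6)
  expect_lt(max(tot), 9e4 * 1.6)
})

test_that("parameter linkage: endpoints, zero slopes, monotonicity", {
  cfg <- small_cfg()
  g <- generate_parcels(cfg)
  truth <- link_parameters(g$parcels, cfg)
  expect_true(all(truth$sigma_e >= 3 & truth$sigma_e <= 4.5))
  expect_true(all(truth$sigma_a >= 3 & truth$sigma_a <= 7))
  ## subject at cohort-max parietal share is at/near the narrow end
  imax <- which.max(truth$parietal_share)
  expect_lt(truth$sigma_e[imax], 3.3)

  cfg0 <- small_cfg(slope_e = 0, slope_a = 0)
  truth0 <- link_parameters(g$parcels, cfg0)
  expect_true(all(truth0$sigma_e == 3.75))
  expect_true(all(truth0$sigma_a == 5))

  ## monotone map: rank correlation is exactly -1 before clipping
  cfg_small_slope <- small_cfg(slope_e = 0.1, slope_a = 0.1)
  t2 <- link_parameters(g$parcels, cfg_small_slope)
  expect_equal(cor(rank(t2$parietal_share), rank(t2$sigma_e)), -1)
  expect_equal(cor(rank(t2$frontal_share), rank(t2$sigma_a)), -1)
})

test_that("true thresholds inherit model structure and respond to linkage", {
  cfg0 <- small_cfg(slope_e = 0, slope_a = 0, threshold_noise_sd = 0)
  g <- generate_parcels(cfg0)
  truth0 <- link_parameters(g$parcels, cfg0)
  thr0 <- generate_true_thresholds(truth0, cfg0)
  ## zero noise + identical parameters: identical thresholds across subjects
  spread <- tapply(thr0$true_ms, thr0$condition, function(v) diff(range(v)))
  expect_true(all(spread < 1e-9))

  ## high-contrast thresholds non-decreasing in size for every subject
  cfg <- small_cfg()
  truth <- link_parameters(g$parcels, cfg)
  thr <- generate_true_thresholds(truth, cfg)
  hi <- thr[grepl("_c0.98", thr$condition, fixed = TRUE), ]
  wide <- thresholds_ord <- reshape(hi, idvar = "subject_id",
                                    timevar = "condition", direction = "wide")
  ## modest noise cannot reverse the ~20 ms suppression gap to the large size
  expect_true(all(wide[["true_ms.size6_c0.98"]] >
                    wide[["true_ms.size0.5_c0.98"]] * 0.8))

  ## cohort-level sign pattern: parietal share vs small high-contrast
  ## threshold negative; frontal share vs large low-contrast negative
  cfgn <- cohort_config(n_subjects = 40L, n_parcels_per_hemi = 20L, seed = 9)
  gn <- generate_parcels(cfgn)
  tn <- link_parameters(gn$parcels, cfgn)
  thn <- generate_true_thresholds(tn, cfgn)
  wn <- reshape(thn, idvar = "subject_id", timevar = "condition",
                direction = "wide")
  wn <- wn[match(tn$subject_id, wn$subject_id), ]
  expect_lt(cor(tn$parietal_share, wn[["true_ms.size0.5_c0.98"]]), 0)
  expect_lt(cor(tn$frontal_share, wn[["true_ms.size6_c0.03"]]), 0)
})

test_that("trial simulation: determinism, recovery, rising-staircase phenotype", {
  cfg <- cohort_config(n_subjects = 10L, n_parcels_per_hemi = 20L, seed = 11,
                       bad_fraction = 0.3, bad_staircase_prob = 1)
  g <- generate_parcels(cfg)
  truth <- link_parameters(g$parcels, cfg)
  thr <- generate_true_thresholds(truth, cfg)
  s1 <- simulate_trials(truth, thr, cfg)
  s2 <- simulate_trials(truth, thr, cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$trials), 10 * 6 * 4 * 25)

  est <- estimate_thresholds(s1$trials)
  sj <- merge(est$subjects, s1$truth[, c("subject_id", "good")],
              by = "subject_id")
  ## every always-guessing-late observer accumulates >= 4 flags
  expect_true(all(sj$exclusion_candidate[!sj$good]))
  ## good observers' final thresholds track the injected truth
  good_thr <- merge(est$thresholds,
                    thr[thr$subject_id %in% s1$truth$subject_id[s1$truth$good], ],
                    by = c("subject_id", "condition"))
  relerr <- abs(good_thr$threshold_ms - good_thr$true_ms) / good_thr$true_ms
  expect_gt(mean(relerr < 0.25), 0.9)
})

test_that("fMRI simulation: pipeline identity without noise, linkage recovery, spikes", {
  cfg <- cohort_config(n_subjects = 10L, n_parcels_per_hemi = 20L, seed = 13,
                       fmri_amp_sd = 0, fmri_tr_noise = 0)
  g <- generate_parcels(cfg)
  truth <- link_parameters(g$parcels, cfg)
  fm <- simulate_fmri(truth, cfg, spike_run_prob = 0, low_hit_prob = 0)
  ## noiseless, spike-free: recovered high-contrast magnitude ~= injected amp
  for (i in c(1, 5, 10)) {
    res <- extract_subject_responses(fm$runs[[i]])$responses
    expect_equal(res$mean_response_pct[res$condition == "high"],
                 fm$truth$hmt_amp[i], tolerance = 0.1)
    expect_equal(res$mean_response_pct[res$condition == "low"],
                 0.5 * fm$truth$hmt_amp[i], tolerance = 0.1)
  }

  ## cohort linkage: frontal share correlates positively, parietal near zero
  cfg2 <- cohort_config(n_subjects = 24L, n_parcels_per_hemi = 20L, seed = 14,
                        fmri_amp_sd = 0.05, fmri_tr_noise = 0.05)
  g2 <- generate_parcels(cfg2)
  t2 <- link_parameters(g2$parcels, cfg2)
  fm2 <- simulate_fmri(t2, cfg2, spike_run_prob = 0, low_hit_prob = 0)
  mag <- vapply(fm2$runs, function(rs) {
    r <- extract_subject_responses(rs)$responses
    mean(r$mean_response_pct)
  }, numeric(1))
  expect_gt(cor(fm2$truth$frontal_share, mag), 0.5)
  expect_lt(abs(cor(fm2$truth$parietal_share, mag)),
            cor(fm2$truth$frontal_share, mag))

  ## blocks overlapping an injected FD spike are excluded
  tc <- fm$runs[[1]][[1]]
  tc$fd_mm[tc$onsets[3]] <- 1.5
  expect_identical(block_motion_qc(tc, tc$onsets[3]), "exclude")
  expect_identical(block_motion_qc(tc, tc$onsets[6]), "keep")
})

test_that("simulate_study presets wire everything together deterministically", {
  s1 <- simulate_study("exp2", seed = 21, n = 10)
  expect_setequal(unique(s1$trials$condition), gap_label(c(0.5, 1, 1.5, 2.5, 4.5)))
  s2 <- simulate_study("exp2", seed = 21, n = 10)
  expect_identical(s1$trials, s2$trials)

  s4 <- simulate_study("exp4", seed = 21, n = 8)
  expect_length(s4$fmri_runs, 8)
  expect_s3_class(s4$fmri_runs[[1]][[1]], "block_timecourse")

  sn <- simulate_study("null", seed = 21, n = 10)
  expect_true(all(sn$truth$sigma_e == 3.75))
  expect_true(all(sn$truth$good))
})
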