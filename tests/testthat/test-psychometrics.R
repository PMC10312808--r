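test_that("Weibull psychometric function: floor, asymptote, closed-form value", {
  p <- weibull_params(100, 3)
  expect_equal(weibull_p_correct(0, p), 0.5)
  expect_equal(weibull_p_correct(1e6, p), 0.96, tolerance = 1e-9)
  ## 0.5 + 0.46 * (1 - exp(-1)), written out independently
  expect_equal(weibull_p_correct(100, p), 0.5 + 0.46 * (1 - exp(-1)),
               tolerance = 1e-12)
  expect_equal(weibull_p_correct(100, p), 0.7908, tolerance = 5e-5)
})

test_that("weibull_p_correct is strictly increasing for random valid params", {
  set.seed(11)
  for (i in 1:25) {
    p <- weibull_params(runif(1, 5, 400), runif(1, 0.6, 10))
    ## sample across the resolvable transition region (far tails are
    ## numerically flat in double precision), via the closed-form inverse
    crits <- sort(runif(50, 0.505, 0.955))
    x <- vapply(crits, function(cr) invert_weibull_threshold(p, cr), numeric(1))
    expect_true(all(diff(x) > 0))
    expect_true(all(diff(weibull_p_correct(x, p)) > 0))
  }
})

test_that("threshold inversion: closed form, round trip, domain errors", {
  p <- weibull_params(100, 3)
  expect_equal(invert_weibull_threshold(p, 0.8), 101.83, tolerance = 1e-4)
  expect_equal(weibull_p_correct(invert_weibull_threshold(p, 0.8), p), 0.8,
               tolerance = 1e-9)
  ## criterion -> gamma+ gives vanishing durations
  eps <- c(1e-2, 1e-4, 1e-8, 1e-12)
  ts <- vapply(eps, function(e) invert_weibull_threshold(p, 0.5 + e), numeric(1))
  expect_true(all(diff(ts) < 0))
  expect_lt(ts[4], 1e-1)
  expect_error(invert_weibull_threshold(p, 0.97), "criterion")
  expect_error(invert_weibull_threshold(p, 0.5), "criterion")

  set.seed(12)
  for (i in 1:200) {
    p <- weibull_params(runif(1, 5, 400), runif(1, 0.6, 10))
    crit <- runif(1, p$gamma + 1e-3, 1 - p$lam - 1e-3)
    x <- invert_weibull_threshold(p, crit)
    expect_equal(weibull_p_correct(x, p), crit, tolerance = 1e-9)
  }
})

test_that("observer_from_threshold places the criterion point exactly", {
  obs <- observer_from_threshold(42, 2.5)
  expect_equal(invert_weibull_threshold(obs), 42, tolerance = 1e-12)
})

test_that("psi posterior updates follow Bayes and commute", {
  st <- psi_init()
  x <- st$lattice[10]
  s1 <- psi_update(st, x, TRUE)
  expect_equal(sum(s1$posterior), 1, tolerance = 1e-12)
  expect_true(all(s1$posterior >= 0))

  ## brute-force Bayes on a tiny 3-alpha grid: correct at small x favors
  ## small alpha
  st3 <- psi_init(n_alpha = 3L, n_beta = 1L, beta_range = c(3, 3))
  xs <- st3$lattice[1]
  s3 <- psi_update(st3, xs, TRUE)
  lik <- weibull_p_correct(xs, weibull_params(1, 3)) # placeholder shape
  lik3 <- vapply(st3$alpha_grid,
                 function(a) weibull_p_correct(xs, weibull_params(a, 3)),
                 numeric(1))
  expect_equal(as.vector(s3$posterior), lik3 / sum(lik3), tolerance = 1e-12)
  mean_before <- sum(st3$posterior[, 1] * st3$alpha_grid)
  mean_after <- sum(s3$posterior[, 1] * st3$alpha_grid)
  expect_lt(mean_after, mean_before)

  ## likelihood product commutes
  a <- psi_update(psi_update(st, x, TRUE), st$lattice[20], FALSE)
  b <- psi_update(psi_update(st, st$lattice[20], FALSE), x, TRUE)
  expect_equal(a$posterior, b$posterior, tolerance = 1e-12)

  expect_error(psi_update(st, 12.34567, TRUE), "lattice")
})

test_that("stimulus selection minimizes expected entropy (exhaustive check)", {
  st <- psi_init(n_alpha = 5L, n_beta = 2L)
  set.seed(3)
  w <- runif(10); w <- w / sum(w)
  st$posterior <- matrix(w, 5, 2)
  eh <- vapply(seq_along(st$lattice), function(i) {
    oracle_expected_entropy(NULL, as.vector(st$posterior), st$plook[i, ])
  }, numeric(1))
  expect_equal(psi_select_stimulus(st), st$lattice[which.min(eh)])

  ## degenerate posterior: selection is a fixed point under repetition
  stdeg <- psi_init(n_alpha = 5L, n_beta = 2L)
  m <- matrix(1e-12, 5, 2); m[3, 1] <- 1
  stdeg$posterior <- m / sum(m)
  x1 <- psi_select_stimulus(stdeg)
  expect_identical(psi_select_stimulus(stdeg), x1)

  ## exact ties break toward the shorter duration
  st2 <- psi_init(n_alpha = 2L, n_beta = 1L, beta_range = c(3, 3),
                  alpha_range = c(50, 100), lattice = c(50, 100))
  st2$plook <- matrix(c(0.7, 0.3, 0.3, 0.7), 2, 2)  # symmetric outcomes
  st2$posterior <- matrix(c(0.5, 0.5), 2, 1)
  expect_equal(psi_select_stimulus(st2), 50)
})

test_that("run_staircase is deterministic and respects lattice bounds", {
  obs <- observer_from_threshold(30, 3)
  r1 <- run_staircase(obs, rng_seed = 7)
  r2 <- run_staircase(obs, rng_seed = 7)
  expect_identical(r1$trials, r2$trials)
  expect_equal(nrow(r1$trials), 25)
  st <- psi_init()
  expect_true(all(r1$trials$duration_ms >= min(st$lattice) - 1e-9 &
                    r1$trials$duration_ms <= max(st$lattice) + 1e-9))

  ## observer far below the lattice floor: nearly all correct, estimates
  ## pile at the bottom of the grid
  easy <- observer_from_threshold(1, 3)
  re <- run_staircase(easy, rng_seed = 8)
  expect_gt(mean(re$trials$correct), 0.9)
  expect_lt(utils::tail(re$trials$running_estimate_ms, 1), 12)
})

test_that("batch simulator agrees with the single-staircase API", {
  obs <- observer_from_threshold(45, 3)
  r1 <- run_staircase(obs, rng_seed = 99)
  b <- run_staircases_batch(alpha = obs$alpha, beta = obs$beta, rng_seed = 99)
  expect_equal(r1$trials$duration_ms, b$duration[, 1])
  expect_equal(r1$trials$correct, b$correct[, 1])
  expect_equal(r1$trials$running_estimate_ms, b$estimate[, 1])
})

test_that("ML Weibull fit recovers a known observer and is sample-scale invariant", {
  set.seed(21)
  truth <- weibull_params(60, 3)
  ## durations concentrated around the transition, as a staircase delivers;
  ## 2000 trials put the threshold's sampling error safely inside 5%
  x <- runif(2000, 20, 180)
  y <- runif(2000) < weibull_p_correct(x, truth)
  rec <- data.frame(duration_ms = x, correct = y)
  fit <- fit_weibull_ml(rec)
  expect_equal(fit$threshold_ms, invert_weibull_threshold(truth),
               tolerance = 0.05)
  expect_identical(fit$status, "ok")

  ## duplicating every trial cannot move the point estimate
  rec2 <- rbind(rec, rec)
  expect_equal(fit_weibull_ml(rec2)$threshold_ms, fit$threshold_ms,
               tolerance = 1e-5)

  ## a 25-trial simulator record yields a finite in-range threshold
  r <- run_staircase(observer_from_threshold(40, 3), rng_seed = 5)
  f25 <- suppressWarnings(fit_weibull_ml(r))
  expect_true(is.finite(f25$threshold_ms))
  expect_gt(f25$threshold_ms, 1)
  expect_lt(f25$threshold_ms, 1000)

  ## all-correct record is flagged as a boundary fit
  recb <- data.frame(duration_ms = rep(100, 12), correct = rep(TRUE, 12))
  expect_warning(fb <- fit_weibull_ml(recb), "boundary")
  expect_identical(fb$status, "boundary")
})

test_that("simulated-observer recovery is accurate at modest scale", {
  set.seed(31)
  n_obs <- 40
  alpha <- runif(n_obs, 20, 200)
  tru <- vapply(alpha, function(a) invert_weibull_threshold(weibull_params(a, 3)),
                numeric(1))
  b <- run_staircases_batch(alpha = rep(alpha, each = 4), beta = 3,
                            rng_seed = 32)
  est <- vapply(seq_len(n_obs), function(i) {
    per_run <- vapply(1:4, function(k) {
      j <- (i - 1) * 4 + k
      rec <- data.frame(duration_ms = b$duration[, j], correct = b$correct[, j])
      suppressWarnings(fit_weibull_ml(rec))$threshold_ms
    }, numeric(1))
    final_threshold(per_run)
  }, numeric(1))
  expect_lt(median(abs(est - tru) / tru), 0.15)
})
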