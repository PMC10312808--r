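test_that("stimulus drive is a contrast-weighted indicator", {
  grid <- spatial_grid(20, 0.5, 2, allow_small = TRUE)
  zero <- build_stimulus_drive(stimulus_spec(extent = 2, contrast = 0), grid)
  expect_true(all(zero == 0))

  d <- build_stimulus_drive(stimulus_spec(extent = 2, contrast = 0.98), grid)
  on <- abs(grid$positions) <= 1
  expect_equal(d[on, 1], rep(0.98, sum(on)))
  expect_true(all(d[!on, 1] == 0) && all(d[, 2] == 0))

  ## center + same-direction surround: bar plus symmetric annulus, zero gap
  stim <- stimulus_spec(extent = 2, contrast = 0.5,
                        surround = list(gap = 1, outer_extent = 4,
                                        direction = "left"))
  ds <- build_stimulus_drive(stim, grid)
  expected <- ifelse(abs(grid$positions) <= 1 |
                       (abs(grid$positions) >= 2 & abs(grid$positions) <= 4),
                     0.5, 0)
  expect_equal(ds[, 1], expected)
  expect_true(all(ds[, 2] == 0))
})

test_that("stimuli violating the guard margin are rejected by name", {
  grid <- spatial_grid(20, 0.5, 2, guard = 5, allow_small = TRUE)
  expect_error(build_stimulus_drive(stimulus_spec(extent = 32, contrast = 1), grid),
               "guard margin")
})

test_that("excitatory convolution: point response, sum conservation, width scaling", {
  grid <- spatial_grid(40, 0.25, 2)
  p <- default_model_params()
  z <- excitatory_drive(matrix(0, length(grid$positions), 2), p, grid)
  expect_true(all(z == 0))

  ## single nonzero sample -> sampled Gaussian with closed-form peak
  img <- matrix(0, length(grid$positions), 2)
  ic <- which(grid$positions == 0)
  img[ic, 1] <- 0.7
  E <- excitatory_drive(img, p, grid)
  expect_equal(E[ic, 1], 0.7 * grid$spacing / (p$excit_width * sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_equal(sum(E[, 1]), 0.7, tolerance = 1e-6)     # unit-area kernel
  expect_true(all(E[, 2] == 0))                        # no channel mixing

  E2 <- excitatory_drive(img, default_model_params(excit_width = 7.5), grid)
  expect_equal(max(E2[, 1]) / max(E[, 1]), 0.5, tolerance = 1e-6)
  expect_equal(sum(E2[, 1]), sum(E[, 1]), tolerance = 1e-6)
})

test_that("suppressive drive pools directions and is broader and lower", {
  grid <- spatial_grid(40, 0.25, 2)
  p <- default_model_params()
  img <- matrix(0, length(grid$positions), 2)
  ic <- which(grid$positions == 0)
  img[ic, 1] <- 1
  E <- excitatory_drive(img, p, grid)
  S <- suppressive_drive(E, p, grid)
  expect_lt(max(S), max(E))
  halfw <- function(v) sum(v > max(v) / 2) * grid$spacing
  expect_gt(halfw(S[, 1]), halfw(E[, 1]))
  expect_equal(S[, 1], S[, 2])                         # broadcast untuned

  ## two equal-energy inputs on different channels == their sum on one
  img2 <- img; img2[ic, 1] <- 0.4; img2[ic, 2] <- 0.6
  img3 <- matrix(0, length(grid$positions), 2); img3[ic, 1] <- 1
  expect_equal(suppressive_drive(excitatory_drive(img2, p, grid), p, grid),
               suppressive_drive(excitatory_drive(img3, p, grid), p, grid),
               tolerance = 1e-12)

  expect_error(suppressive_drive(E, default_model_params(excit_width = 4.4,
                                                         suppress_width = 4.4), grid),
               "exceed")
})

test_that("attention field: identity at amplitude 1, peak at center, width ordering", {
  grid <- spatial_grid(40, 0.25, 2)
  stim <- stimulus_spec(extent = 2, contrast = 0.5)
  A1 <- attention_field(stim, default_model_params(attn_amplitude = 1), grid)
  expect_true(all(A1 == 1))

  p <- default_model_params(attn_amplitude = 2.5)
  A <- attention_field(stim, p, grid)
  ic <- which(grid$positions == 0)
  expect_equal(A[ic, 1], 2.5)
  expect_true(min(A) >= 1)

  An <- attention_field(stim, default_model_params(attn_width = 3), grid)
  Aw <- attention_field(stim, default_model_params(attn_width = 7), grid)
  off <- abs(grid$positions) > 1
  expect_true(all(An[off, 1] <= Aw[off, 1]))
  expect_equal(An[ic, 1], Aw[ic, 1])
  expect_error(attention_field(stim, within(p, attn_amplitude <- 0.5), grid))
})

test_that("population response and scalar readout match brute force", {
  grid <- spatial_grid(2, 1, 2, allow_small = TRUE)   # 5 samples
  p <- default_model_params(sigma = 0.3)
  set.seed(5)
  E <- matrix(runif(10), 5, 2)
  A <- matrix(runif(10, 1, 2), 5, 2)
  S <- matrix(runif(10, 0.1, 1), 5, 2)
  R <- population_response(E, S, A, p)
  for (i in 1:5) for (j in 1:2) {
    expect_equal(R[i, j], A[i, j] * E[i, j] / (S[i, j] + p$sigma))
  }
  expect_equal(model_response(R), max(as.vector(R)))
  expect_equal(model_response(matrix(0, 3, 2)), 0)
  m <- matrix(0, 3, 2); m[2, 2] <- 0.7
  expect_equal(model_response(m), 0.7)
  expect_error(population_response(E, S, A, within(p, sigma <- 0)))
  expect_equal(population_response(matrix(0, 5, 2), S, A, p),
               matrix(0, 5, 2))
})

test_that("predicted threshold is inverse response with explicit zero handling", {
  p <- default_model_params(scale_k = 50)
  expect_equal(predict_threshold(0.5, p), 100)
  expect_equal(predict_threshold(1, p), 2 * predict_threshold(2, p))
  expect_error(predict_threshold(0, p), "zero")
  expect_identical(predict_threshold(0, p, on_zero = "inf"), Inf)
})

test_that("every stage matches the nested-loop oracle on a tiny grid", {
  grid <- spatial_grid(7, 1, 2, allow_small = TRUE)   # 15 samples
  for (ew in c(1.5, 2)) {
    p <- default_model_params(excit_width = ew, suppress_width = 3.5,
                              sigma = 0.05)
    stim <- stimulus_spec(extent = 3, contrast = 0.8, direction = "right")
    ora <- oracle_model_response(stim, p, grid)
    D <- build_stimulus_drive(stim, grid)
    E <- excitatory_drive(D, p, grid)
    A <- attention_field(stim, p, grid)
    S <- suppressive_drive(A * E, p, grid)
    R <- population_response(E, S, A, p)
    expect_equal(E, ora$E, tolerance = 1e-9)
    expect_equal(S, ora$S, tolerance = 1e-9)
    expect_equal(R, ora$R, tolerance = 1e-9)
    expect_equal(model_response(R), ora$response, tolerance = 1e-9)
  }
})

test_that("orderings O1-O3 hold at the shipped calibrated defaults", {
  pg <- function(ew, aw) {
    predict_condition_grid(default_model_params(excit_width = ew, attn_width = aw))
  }
  lo <- function(d) d$predicted_ms[d$contrast == 0.03]
  hi <- function(d) d$predicted_ms[d$contrast == 0.98]
  mid <- pg(3.75, 5); eN <- pg(3, 5); eW <- pg(4.5, 5)
  aN <- pg(3.75, 3); aW <- pg(3.75, 7)

  ## O1: surround suppression -- high-contrast threshold non-decreasing in size
  for (d in list(mid, eN, eW, aN, aW)) expect_true(all(diff(hi(d)) >= 0))

  ## O2: narrowing excitatory width helps small, not large, low-contrast sizes
  de <- lo(eW) - lo(eN)
  expect_gt(de[1], 0)
  expect_lt(abs(de[3]), 0.1 * de[1])

  ## O3: narrowing attention width helps most at the large low-contrast size
  da <- lo(aW) - lo(aN)
  expect_gt(da[3], da[1])
  expect_gt(da[3], 0)

  ## higher contrast never raises the threshold at the smallest size
  sweep <- predict_condition_grid(default_model_params(), sizes_deg = 0.5,
                                  contrasts = c(0.03, 0.2, 0.5, 0.98))
  expect_true(all(diff(sweep$predicted_ms) <= 0))
})

test_that("halving the grid spacing changes predictions by < 1%", {
  p <- default_model_params()
  a <- predict_condition_grid(p, spacing = 0.05)
  b <- predict_condition_grid(p, spacing = 0.025)
  expect_lt(max(abs(b$predicted_ms / a$predicted_ms - 1)), 0.01)
})

test_that("parameter validation enforces the model's structural constraints", {
  expect_error(model_params(excit_width = 5, suppress_width = 4), "broader")
  expect_error(model_params(attn_amplitude = 0.9), ">= 1")
  expect_error(stimulus_spec(extent = 2, contrast = 1.2))
  expect_error(stimulus_spec(extent = 2, contrast = 0.5,
                             surround = list(gap = 1, outer_extent = 1.5,
                                             direction = "left")),
               "outer_extent")
})
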