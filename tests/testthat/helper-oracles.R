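## Independent brute-force oracles and fixture builders. Everything here is
## deliberately naive (nested loops, direct formulas) and stays independent
## of the package's computation paths.

## Naive zero-padded Gaussian convolution: direct double sum over samples.
oracle_conv_gauss <- function(mat, sigma, grid) {
  pos <- grid$positions
  n <- length(pos)
  out <- matrix(0, n, ncol(mat))
  for (j in seq_len(ncol(mat))) {
    for (i in seq_len(n)) {
      acc <- 0
      for (k in seq_len(n)) {
        acc <- acc + mat[k, j] * dnorm(pos[i] - pos[k], sd = sigma) * grid$spacing
      }
      out[i, j] <- acc
    }
  }
  out
}

## Full model pipeline via nested loops only (mirrors the documented math).
oracle_model_response <- function(stim, params, grid) {
  D <- build_stimulus_drive(stim, grid)
  E <- oracle_conv_gauss(D, params$excit_width, grid)
  a <- 1 + (params$attn_amplitude - 1) *
    exp(-(grid$positions - stim$center)^2 / (2 * params$attn_width^2))
  A <- matrix(a, length(a), ncol(D))
  AE <- A * E
  pooled <- rowSums(AE)
  S1 <- oracle_conv_gauss(matrix(pooled, ncol = 1), params$suppress_width, grid)
  S <- matrix(as.vector(S1), nrow(AE), ncol(AE))
  R <- AE / (S + params$sigma)
  best <- -Inf
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R))) {
    if (R[i, j] > best) best <- R[i, j]
  }
  list(E = E, S = S, A = A, R = R, response = best)
}

## Expected posterior entropy by explicit enumeration over outcomes and
## grid points, for one candidate duration.
oracle_expected_entropy <- function(p_correct_given_grid, w, x_prob_row) {
  pc <- sum(x_prob_row * w)
  post_c <- x_prob_row * w / pc
  post_i <- (1 - x_prob_row) * w / (1 - pc)
  H <- function(v) -sum(v * log(v))
  pc * H(post_c) + (1 - pc) * H(post_i)
}

## Constructed staircase records for QC tests.
## Converging: strictly decreasing estimates with last-5/first-10 < 0.8.
make_converging_record <- function(start_ms, end_ms, n = 25) {
  stopifnot(end_ms < 0.7 * start_ms)
  est <- exp(seq(log(start_ms), log(end_ms), length.out = n))
  staircase_record("conv", duration_ms = pmax(est, 6.7),
                   correct = rep(c(TRUE, TRUE, FALSE), length.out = n),
                   running_estimate_ms = est)
}

## Rising: estimates increase by >= 25% from the first-10 mean.
make_rising_record <- function(start_ms, rise_factor = 1.6, n = 25) {
  stopifnot(rise_factor >= 1.25)
  est <- c(seq(start_ms, start_ms * 0.95, length.out = 10),
           seq(start_ms, start_ms * rise_factor, length.out = n - 10))
  staircase_record("rise", duration_ms = pmax(est, 6.7),
                   correct = rep(c(TRUE, FALSE), length.out = n),
                   running_estimate_ms = est)
}

## Small tidy parcel fixture: 2 subjects x 2 hemis x k parcels.
make_parcel_fixture <- function(k = 4, seed = 1) {
  set.seed(seed)
  df <- expand.grid(subject_id = c("A", "B"), hemi = c("LH", "RH"),
                    parcel = paste0("p", seq_len(k)),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$value <- runif(nrow(df), 200, 800)
  parcel_table(df, "raw")
}

## FreeSurfer anatomical-stats-style text for one subject/hemisphere.
write_fs_stats_fixture <- function(path, parcels, areas) {
  lines <- c(
    "# Table of FreeSurfer cortical parcellation anatomical statistics",
    "# anatomy_type surface",
    "# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg",
    sprintf("%s  %d  %.6f  %.1f  %.3f", parcels,
            seq_along(parcels) * 100L, areas, areas * 2.5,
            2 + seq_along(parcels) / 10))
  writeLines(lines, path)
  path
}

## Textbook Pearson r and t-test p, written directly from the formulas.
oracle_pearson <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  r <- num / den
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), df = n - 2))
}
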