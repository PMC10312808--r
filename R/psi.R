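#' Staircase record
#'
#' One adaptive staircase: an ordered sequence of trials with the presented
#' duration, the response outcome, and the running threshold estimate after
#' each trial. The running estimate is the posterior mean of alpha.
#'
#' @param condition Condition label (e.g. `"size0.5_c0.98"`).
#' @param duration_ms Presented durations.
#' @param correct Logical (or 0/1) response outcomes.
#' @param running_estimate_ms Running threshold estimates, same length.
#' @return An object of class `staircase_record` with fields `condition`
#'   and `trials` (a data frame).
#' @export
staircase_record <- function(condition, duration_ms, correct,
                             running_estimate_ms) {
  stopifnot(length(duration_ms) == length(correct),
            length(duration_ms) == length(running_estimate_ms),
            all(duration_ms > 0))
  structure(list(condition = condition,
                 trials = data.frame(
                   trial = seq_along(duration_ms),
                   duration_ms = duration_ms,
                   correct = as.logical(correct),
                   running_estimate_ms = running_estimate_ms)),
            class = "staircase_record")
}

#' @export
print.staircase_record <- function(x, ...) {
  cat(sprintf("<staircase_record> condition '%s', %d trials, final estimate %.1f ms\n",
              x$condition, nrow(x$trials),
              utils::tail(x$trials$running_estimate_ms, 1)))
  invisible(x)
}

#' Initialize a Psi adaptive-staircase state
#'
#' Bayesian adaptive threshold estimation in the Kontsevich–Tyler style: a
#' posterior over a log-spaced alpha x beta lattice of Weibull parameters
#' (guess and lapse fixed) is updated after every trial, and the next
#' duration is the one minimizing the expected posterior entropy. The
#' stimulus lattice defaults to the alpha grid, spanning the 6.7–333 ms
#' presentation range.
#'
#' @param alpha_range Range of the alpha grid, ms (default `c(6.7, 333)`).
#' @param n_alpha Number of log-spaced alpha values (default 41).
#' @param beta_range Range of the beta grid (default `c(0.5, 16)`).
#' @param n_beta Number of log-spaced beta values (default 21).
#' @param gamma,lam Fixed guess and lapse rates.
#' @param lattice Admissible stimulus durations, ms; defaults to the alpha
#'   grid. Must lie within `alpha_range`.
#' @return An object of class `psi_state`: grids, a uniform prior
#'   `posterior` (alpha x beta matrix), the `lattice`, and a precomputed
#'   probability-correct array `plook` (lattice x flattened grid).
#' @export
psi_init <- function(alpha_range = c(6.7, 333), n_alpha = 41L,
                     beta_range = c(0.5, 16), n_beta = 21L,
                     gamma = 0.5, lam = 0.04, lattice = NULL) {
  alpha_grid <- exp(seq(log(alpha_range[1]), log(alpha_range[2]),
                        length.out = n_alpha))
  beta_grid <- exp(seq(log(beta_range[1]), log(beta_range[2]),
                       length.out = n_beta))
  if (is.null(lattice)) lattice <- alpha_grid
  lattice <- sort(lattice)
  if (min(lattice) < alpha_range[1] - 1e-9 || max(lattice) > alpha_range[2] + 1e-9) {
    stop("stimulus lattice must lie within alpha_range")
  }
  posterior <- matrix(1 / (n_alpha * n_beta), n_alpha, n_beta)
  ## plook[i, g]: p(correct | lattice[i], grid point g), grid flattened
  ## with alpha varying fastest (column-major over alpha x beta)
  ab <- expand.grid(alpha = alpha_grid, beta = beta_grid)
  plook <- matrix(NA_real_, length(lattice), nrow(ab))
  for (i in seq_along(lattice)) {
    plook[i, ] <- gamma + (1 - gamma - lam) *
      (1 - exp(-(lattice[i] / ab$alpha)^ab$beta))
  }
  structure(list(alpha_grid = alpha_grid, beta_grid = beta_grid,
                 gamma = gamma, lam = lam, lattice = lattice,
                 posterior = posterior, plook = plook),
            class = "psi_state")
}

psi_likelihood_row <- function(state, x) {
  i <- which(abs(state$lattice - x) < 1e-9)
  if (length(i) != 1) stop("duration is not on the stimulus lattice")
  state$plook[i, ]
}

#' Bayesian posterior update after one trial
#'
#' Multiplies the posterior pointwise by the Bernoulli likelihood of the
#' observed outcome under each (alpha, beta) and renormalizes.
#'
#' @param state A [psi_init()] state.
#' @param x Presented duration (must be on the lattice).
#' @param correct Logical outcome.
#' @return The updated `psi_state`.
#' @export
psi_update <- function(state, x, correct) {
  lik <- psi_likelihood_row(state, x)
  if (!correct) lik <- 1 - lik
  w <- as.vector(state$posterior) * lik
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0) stop("posterior mass vanished in psi_update")
  state$posterior <- matrix(w / tot, nrow(state$posterior), ncol(state$posterior))
  state
}

#' Select the next stimulus by expected-entropy minimization
#'
#' For each lattice duration, computes the posterior entropy expected after
#' the trial (over both possible outcomes) and returns the duration with
#' the smallest expected entropy; ties break toward the shorter duration.
#'
#' @param state A [psi_init()] state.
#' @return A duration in ms (an element of `state$lattice`).
#' @export
psi_select_stimulus <- function(state) {
  w <- as.vector(state$posterior)
  eh <- psi_expected_entropy(state$plook, w)
  state$lattice[which.min(eh)]
}

## Expected posterior entropy for every lattice level given posterior w.
## Up to an additive constant (the current entropy term sum w log w, which
## does not depend on the candidate level),
##   EH[i] = -(A1[i] + B1[i]) + pc*log(pc) + qc*log(qc),
## with A1 = sum_g P[i,g] w_g log P[i,g], B1 likewise for Q = 1 - P, and
## pc = sum_g P[i,g] w_g. The constant is included so the value is the true
## expected entropy (useful for oracle comparison).
psi_expected_entropy <- function(plook, w) {
  pc <- as.vector(plook %*% w)
  qc <- 1 - pc
  A1 <- as.vector((plook * log(plook)) %*% w)
  B1 <- as.vector(((1 - plook) * log1p(-plook)) %*% w)
  cs <- sum(w * log(w))
  -(A1 + B1 + cs) + pc * log(pc) + qc * log(qc)
}

#' Running threshold estimate from a Psi state
#'
#' Posterior mean of alpha (the toolbox convention). Under the uniform
#' prior this starts near the arithmetic mean of the alpha grid (~83 ms for
#' the 6.7-333 ms range), well above typical thresholds, so healthy
#' staircases descend -- which is what the last-5/first-10 quality-control
#' ratio assumes.
#'
#' @param state A [psi_init()] state.
#' @return Estimate in ms.
#' @export
psi_running_estimate <- function(state) {
  wa <- rowSums(state$posterior)
  sum(wa * state$alpha_grid)
}

#' Simulate one adaptive staircase
#'
#' Runs the Psi trial loop against a simulated Weibull observer: select the
#' duration minimizing expected posterior entropy, draw a Bernoulli
#' response from the observer's psychometric function, update the
#' posterior, and record the running estimate.
#'
#' @param observer A [weibull_params()] describing the simulated observer.
#' @param n_trials Number of trials (default 25).
#' @param rng_seed Optional integer seed for reproducibility.
#' @param state Optional pre-built [psi_init()] state (a fresh default
#'   state is used otherwise).
#' @param condition Condition label stored on the record.
#' @param guess_trials Optional integer vector of trial indices during
#'   which the observer guesses (p = 0.5) regardless of duration; used to
#'   emulate inattentive observers.
#' @return A [staircase_record()].
#' @export
run_staircase <- function(observer, n_trials = 25L, rng_seed = NULL,
                          state = NULL, condition = "cond",
                          guess_trials = integer(0)) {
  stopifnot(inherits(observer, "weibull_params"))
  res <- run_staircases_batch(
    alpha = observer$alpha, beta = observer$beta,
    n_trials = n_trials, gamma = observer$gamma, lam = observer$lam,
    rng_seed = rng_seed, state = state,
    guess_trials = list(guess_trials))
  staircase_record(condition,
                   duration_ms = res$duration[, 1],
                   correct = res$correct[, 1],
                   running_estimate_ms = res$estimate[, 1])
}

#' Simulate many independent staircases at once
#'
#' Vectorized version of [run_staircase()]: all staircases share the Psi
#' configuration but each has its own simulated observer. Selection,
#' response and update steps are computed for all staircases per trial via
#' matrix algebra, which makes cohort-scale simulation fast. Trial `t` of
#' staircase `s` is driven by its own observer, so the result for each
#' staircase is distributed identically to a single [run_staircase()] call
#' (the random-number stream is consumed trial-major).
#'
#' @param alpha,beta Observer Weibull parameters, recycled to a common
#'   length `S` (number of staircases).
#' @param n_trials Trials per staircase.
#' @param gamma,lam Fixed guess and lapse rates.
#' @param rng_seed Optional integer seed.
#' @param state Optional [psi_init()] template.
#' @param guess_trials Optional list of length `S`; element `s` gives trial
#'   indices where observer `s` guesses at p = 0.5.
#' @return A list of matrices `duration`, `correct`, `estimate`, each
#'   `n_trials` x `S`.
#' @export
run_staircases_batch <- function(alpha, beta, n_trials = 25L, gamma = 0.5,
                                 lam = 0.04, rng_seed = NULL, state = NULL,
                                 guess_trials = NULL) {
  S <- max(length(alpha), length(beta))
  alpha <- rep_len(alpha, S); beta <- rep_len(beta, S)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  if (is.null(state)) state <- psi_init(gamma = gamma, lam = lam)
  P <- state$plook                       # n_lat x G
  G <- ncol(P)
  PlogP <- P * log(P)
  QlogQ <- (1 - P) * log1p(-P)
  W <- matrix(1 / G, G, S)
  lat <- state$lattice
  alpha_g <- rep(state$alpha_grid, times = length(state$beta_grid))
  dur <- cor_ <- est <- matrix(NA_real_, n_trials, S)
  for (t in seq_len(n_trials)) {
    PC <- P %*% W                        # n_lat x S
    QC <- 1 - PC
    EH <- -(PlogP %*% W) - (QlogQ %*% W) + PC * log(PC) + QC * log(QC)
    idx <- max.col(-t(EH), ties.method = "first")   # min EH, ties -> shortest
    x <- lat[idx]
    p_true <- gamma + (1 - gamma - lam) * (1 - exp(-(x / alpha)^beta))
    if (!is.null(guess_trials)) {
      guessing <- vapply(guess_trials, function(g) t %in% g, logical(1))
      p_true[guessing] <- 0.5
    }
    y <- stats::runif(S) < p_true
    Pl <- t(P[idx, , drop = FALSE])      # G x S, row gather
    L <- Pl
    L[, !y] <- 1 - L[, !y]
    W <- W * L
    W <- W / rep(colSums(W), each = G)
    dur[t, ] <- x
    cor_[t, ] <- as.numeric(y)
    est[t, ] <- as.vector(crossprod(W, alpha_g))
  }
  list(duration = dur, correct = cor_ == 1, estimate = est)
}
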