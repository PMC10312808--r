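#' Weibull psychometric function parameters
#'
#' Accuracy in the two-alternative direction-discrimination task is modeled
#' as `p(x) = gamma + (1 - gamma - lam) * (1 - exp(-(x/alpha)^beta))` for
#' stimulus duration `x` (ms), with guess rate `gamma` fixed at 0.5 (2AFC)
#' and lapse rate `lam` fixed at 0.04.
#'
#' @param alpha Scale (ms), > 0.
#' @param beta Slope (dimensionless), > 0.
#' @param gamma Guess rate, default 0.5.
#' @param lam Lapse rate, default 0.04; requires `gamma < 1 - lam`.
#' @return An object of class `weibull_params`.
#' @export
weibull_params <- function(alpha, beta, gamma = 0.5, lam = 0.04) {
  stopifnot(alpha > 0, beta > 0, gamma >= 0, lam >= 0)
  if (gamma >= 1 - lam) stop("require gamma < 1 - lam")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, lam = lam),
            class = "weibull_params")
}

#' Probability correct under the Weibull psychometric function
#'
#' @param x Stimulus duration(s), ms, >= 0.
#' @param p A [weibull_params()].
#' @return Probability correct, strictly increasing in `x`, with floor
#'   `gamma` at `x = 0` and asymptote `1 - lam`.
#' @export
weibull_p_correct <- function(x, p) {
  stopifnot(all(x >= 0), inherits(p, "weibull_params"))
  p$gamma + (1 - p$gamma - p$lam) * (1 - exp(-(x / p$alpha)^p$beta))
}

#' Duration at a criterion accuracy (inverse Weibull)
#'
#' Solves `weibull_p_correct(x) = criterion` in closed form:
#' `alpha * (-log(1 - (criterion - gamma)/(1 - gamma - lam)))^(1/beta)`.
#'
#' @param p A [weibull_params()].
#' @param criterion Target probability correct, strictly inside
#'   `(gamma, 1 - lam)`; default 0.80.
#' @return Duration in ms.
#' @export
invert_weibull_threshold <- function(p, criterion = 0.80) {
  stopifnot(inherits(p, "weibull_params"))
  if (criterion <= p$gamma || criterion >= 1 - p$lam) {
    stop(sprintf("criterion must lie strictly inside (%g, %g)",
                 p$gamma, 1 - p$lam))
  }
  p$alpha * (-log(1 - (criterion - p$gamma) / (1 - p$gamma - p$lam)))^(1 / p$beta)
}

#' Observer parameters whose criterion-accuracy duration equals a target
#'
#' Convenience inverse of [invert_weibull_threshold()]: given a desired
#' threshold (duration at `criterion` accuracy) and a slope, returns the
#' `alpha` that places the psychometric function there.
#'
#' @param threshold_ms Target duration at criterion accuracy.
#' @param beta Slope.
#' @param criterion Criterion accuracy (default 0.80).
#' @inheritParams weibull_params
#' @return A [weibull_params()].
#' @export
observer_from_threshold <- function(threshold_ms, beta, criterion = 0.80,
                                    gamma = 0.5, lam = 0.04) {
  base <- weibull_params(1, beta, gamma, lam)
  t1 <- invert_weibull_threshold(base, criterion)
  weibull_params(threshold_ms / t1, beta, gamma, lam)
}

#' Maximum-likelihood Weibull fit to a staircase record
#'
#' Maximizes the Bernoulli likelihood over `(alpha, beta)` with guess and
#' lapse rates fixed, searching `alpha` in log space over `[1, 1000]` ms and
#' `beta` over `[0.5, 16]`. Records in which every response is correct (or
#' every response incorrect) carry no information about the threshold
#' location; the fit then sits on the search boundary and is flagged.
#'
#' @param record A [staircase_record()] or a data frame with columns
#'   `duration_ms` and `correct`.
#' @param gamma,lam Fixed guess and lapse rates.
#' @param criterion Accuracy level at which the threshold is read out
#'   (default 0.80).
#' @return A list with `params` ([weibull_params()]), `threshold_ms`
#'   (duration at `criterion`), `loglik`, and `status` (`"ok"` or
#'   `"boundary"`).
#' @export
fit_weibull_ml <- function(record, gamma = 0.5, lam = 0.04, criterion = 0.80) {
  tr <- if (inherits(record, "staircase_record")) record$trials else record
  x <- tr$duration_ms
  y <- as.integer(tr$correct)
  stopifnot(length(x) >= 10, all(x > 0), all(y %in% c(0L, 1L)))
  lo <- c(log(1), log(0.5))
  hi <- c(log(1000), log(16))
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    pr <- gamma + (1 - gamma - lam) * (1 - exp(-(x / a)^b))
    -sum(y * log(pr) + (1 - y) * log1p(-pr))
  }
  ## coarse log-spaced grid start, then box-constrained quasi-Newton
  a0 <- exp(seq(log(max(min(x), 1)), log(min(max(x) * 4, 1000)), length.out = 9))
  b0 <- c(1, 3, 8)
  starts <- expand.grid(a = log(a0), b = log(b0))
  v <- apply(starts, 1, nll)
  par0 <- as.numeric(starts[which.min(v), ])
  fit <- stats::optim(par0, nll, method = "L-BFGS-B", lower = lo, upper = hi)
  params <- weibull_params(exp(fit$par[1]), exp(fit$par[2]), gamma, lam)
  status <- "ok"
  if (all(y == 1L) || all(y == 0L)) {
    status <- "boundary"
    warning("staircase record is all-correct or all-incorrect; threshold fit is a boundary estimate")
  }
  list(params = params,
       threshold_ms = invert_weibull_threshold(params, criterion),
       loglik = -fit$value, status = status)
}
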