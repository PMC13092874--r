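#' Linear ballistic accumulator parameters
#'
#' Each of three accumulators races linearly from a start point drawn
#' uniformly on `[0, A]` to the threshold `b = A + k`, with a slope drawn from
#' `Normal(v_a, s)`; the first to reach `b` determines choice, and RT is the
#' passage time plus the non-decision time `tau`. The drift-rate variability
#' `s` is fixed at 1 by convention (the scale of the race is identified by the
#' drift magnitudes).
#'
#' @param A Start-point range (> 0).
#' @param k Relative threshold (> 0); threshold is `b = A + k`.
#' @param tau Non-decision time in seconds, in (0,1).
#' @param eta Drift scaling parameter (> 0); see [drift_rates()].
#' @param s Between-trial drift standard deviation (default 1, fixed).
#' @return Object of class `lba_params` with derived field `b`.
#' @export
lba_params <- function(A, k, tau, eta, s = 1) {
  if (!all(is.finite(c(A, k, tau, eta, s)))) stop("non-finite LBA parameter")
  if (A <= 0 || k <= 0 || s <= 0 || eta <= 0) stop("A, k, s, eta must be > 0")
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0,1) seconds")
  structure(list(A = A, k = k, b = A + k, tau = tau, eta = eta, s = s),
            class = "lba_params")
}

#' Drift rates from the action policy and prior entropy
#'
#' The mean drift of accumulator `a` is the policy probability scaled by the
#' trial's drift scaling and divided by the pre-trial uncertainty:
#' `v_a = eta_t * pi_a / H_prior`. High mapping uncertainty (large entropy)
#' slows all accumulators; a concentrated policy speeds its favored one.
#'
#' @param pi Policy probability 3-vector (sums to 1).
#' @param h_prior Prior entropy in bits (>= its floor, > 0).
#' @param eta_t Trial-wise drift scaling (> 0), the fixed `eta` in the
#'   baseline model or `eta + z(CPP slope) * beta_slope` in the neurally
#'   informed model.
#' @return Object of class `drift_vector`: field `v` (3-vector) plus the
#'   inputs.
#' @export
drift_rates <- function(pi, h_prior, eta_t) {
  if (!all(is.finite(pi)) || !is.finite(h_prior) || !is.finite(eta_t))
    stop("non-finite input")
  if (h_prior <= 0 || eta_t <= 0) stop("h_prior and eta_t must be positive")
  structure(list(v = eta_t * pi / h_prior, source_policy = pi,
                 h_prior = h_prior, eta_t = eta_t),
            class = "drift_vector")
}

# First-passage density of a single accumulator at decision time t (> 0):
# start ~ U(0, A), slope ~ N(v, s), threshold b. Brown & Heathcote form.
lba_fpt_pdf <- function(t, b, A, v, s) {
  ts <- t * s
  z1 <- (b - A - t * v) / ts
  z2 <- (b - t * v) / ts
  out <- (-v * stats::pnorm(z1) + s * stats::dnorm(z1) +
            v * stats::pnorm(z2) - s * stats::dnorm(z2)) / A
  out[t <= 0] <- 0
  pmax(out, 0)
}

# First-passage distribution function of a single accumulator.
lba_fpt_cdf <- function(t, b, A, v, s) {
  ts <- t * s
  z1 <- (b - A - t * v) / ts
  z2 <- (b - t * v) / ts
  out <- 1 + (b - A - t * v) / A * stats::pnorm(z1) -
    (b - t * v) / A * stats::pnorm(z2) +
    ts / A * (stats::dnorm(z1) - stats::dnorm(z2))
  out[t <= 0] <- 0
  pmin(pmax(out, 0), 1)
}

#' Defective density of a choice and response time
#'
#' Joint density of responding with `choice` at time `t`: the winning
#' accumulator's first-passage density times the probability that every other
#' accumulator has not yet finished, evaluated at the decision time
#' `t - tau`. Densities are conditioned on at least one accumulator having a
#' positive sampled slope (the same truncation the simulator applies by
#' resampling), so the defective densities sum and integrate to exactly 1 over
#' choices and time. Zero for `t <= tau`.
#'
#' @param t Response time(s) in seconds.
#' @param choice Winning accumulator, 1 to 3.
#' @param drifts A [drift_rates()] object (or list with field `v`).
#' @param params [lba_params()].
#' @return Density value(s).
#' @export
lba_defective_density <- function(t, choice, drifts, params) {
  v <- drifts$v
  stopifnot(length(v) == 3L, choice %in% 1:3)
  td <- t - params$tau
  f <- lba_fpt_pdf(td, params$b, params$A, v[choice], params$s)
  for (j in seq_along(v)[-choice])
    f <- f * (1 - lba_fpt_cdf(td, params$b, params$A, v[j], params$s))
  # renormalize for the all-negative-slope event, excluded by resampling
  p_none <- prod(stats::pnorm(-v / params$s))
  out <- f / (1 - p_none)
  out[td <= 0] <- 0
  out
}

#' Log-likelihood of one (choice, RT) observation
#'
#' Log of [lba_defective_density()], floored at `log(1e-300)` so degenerate
#' observations (e.g. RT at or below the non-decision time) contribute a
#' finite penalty rather than `-Inf`.
#'
#' @inheritParams lba_defective_density
#' @param rt Response time in seconds (finite, > 0).
#' @return Finite log-density.
#' @export
trial_loglik <- function(rt, choice, drifts, params) {
  if (is.na(rt)) stop("rt is missing")
  d <- lba_defective_density(rt, choice, drifts, params)
  max(log(d), log(1e-300))
}

#' Simulate the accumulator race
#'
#' Draws per-accumulator start points `U(0, A)` and slopes `N(v_a, s)`; the
#' winner is the accumulator with positive slope that reaches `b` first, and
#' RT is `tau` plus its passage time. Trials on which no sampled slope is
#' positive are resampled (matching the truncation in the density).
#'
#' @param drifts [drift_rates()] object (or list with `v`).
#' @param params [lba_params()].
#' @param n Number of trials to simulate.
#' @param seed Optional integer seed.
#' @return data.frame with columns `choice` and `rt`.
#' @export
simulate_race <- function(drifts, params, n = 1L, seed = NULL) {
  v <- drifts$v
  stopifnot(length(v) == 3L)
  if (all(v <= 0)) stop("at least one mean drift must be positive")
  if (!is.null(seed)) local_rng(seed)
  choice <- integer(n); rt <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0L) {
    m <- length(todo)
    slopes <- matrix(stats::rnorm(3L * m, mean = rep(v, each = m),
                                  sd = params$s), nrow = m)
    starts <- matrix(stats::runif(3L * m, 0, params$A), nrow = m)
    tt <- (params$b - starts) / slopes
    tt[slopes <= 0] <- Inf
    win <- max.col(-tt, ties.method = "first")
    t_win <- tt[cbind(seq_len(m), win)]
    ok <- is.finite(t_win)
    choice[todo[ok]] <- win[ok]
    rt[todo[ok]] <- params$tau + t_win[ok]
    todo <- todo[!ok]
  }
  data.frame(choice = choice, rt = rt)
}
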