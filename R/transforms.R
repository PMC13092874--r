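# Canonical parameter order shared by the R and C++ code paths.
PARAM_NAMES <- c("alpha_rl", "bias", "phi", "rho", "capacity",
                 "A", "k", "tau", "eta", "beta_slope")

#' Fast approximation to the standard normal CDF
#'
#' Logistic approximation `plogis(0.07056 x^3 + 1.5976 x)`, accurate to about
#' 1.4e-3 over the real line. The exact CDF is used in the package's
#' transforms; this is provided for parity with samplers that rely on the
#' approximation.
#'
#' @param x Numeric vector.
#' @return Approximate `pnorm(x)`.
#' @export
phi_approx <- function(x) stats::plogis(0.07056 * x^3 + 1.5976 * x)

#' Map unconstrained parameters to their natural scale
#'
#' `alpha_rl`, `bias`, `phi`, `rho` and `tau` map through the standard normal
#' CDF onto (0,1); `capacity` maps onto (2,5) via `2 + 3 * pnorm(x)`;
#' `A`, `k` and `eta` are exponentiated; `beta_slope` is unrestricted.
#'
#' @param x Named or ordered numeric vector on the unconstrained scale
#'   (order `alpha_rl, bias, phi, rho, capacity, A, k, tau, eta, beta_slope`;
#'   the trailing `beta_slope` may be omitted and defaults to 0).
#' @return Named numeric vector of length 10 on the constrained scale.
#' @export
constrain_params <- function(x) {
  if (length(x) == 9L) x <- c(x, 0)
  stopifnot(length(x) == 10L)
  x <- unname(x)
  out <- c(
    stats::pnorm(x[1:4]),          # alpha_rl, bias, phi, rho
    2 + 3 * stats::pnorm(x[5]),    # capacity
    exp(x[6:7]),                   # A, k
    stats::pnorm(x[8]),            # tau
    exp(x[9]),                     # eta
    x[10]                          # beta_slope
  )
  stats::setNames(out, PARAM_NAMES)
}

#' Map constrained parameters back to the unconstrained scale
#'
#' Inverse of [constrain_params()], defined on the open parameter domain.
#'
#' @param theta Named or ordered numeric vector on the constrained scale.
#' @return Named numeric vector of length 10 on the unconstrained scale.
#' @export
unconstrain_params <- function(theta) {
  if (length(theta) == 9L) theta <- c(theta, 0)
  stopifnot(length(theta) == 10L)
  theta <- unname(theta)
  if (any(theta[c(1:4, 8)] <= 0 | theta[c(1:4, 8)] >= 1))
    stop("probability-scale parameters must lie strictly in (0,1)")
  if (theta[5] <= 2 || theta[5] >= 5) stop("capacity must lie strictly in (2,5)")
  if (any(theta[c(6, 7, 9)] <= 0)) stop("A, k, eta must be positive")
  out <- c(
    stats::qnorm(theta[1:4]),
    stats::qnorm((theta[5] - 2) / 3),
    log(theta[6:7]),
    stats::qnorm(theta[8]),
    log(theta[9]),
    theta[10]
  )
  stats::setNames(out, PARAM_NAMES)
}

#' Prior specification for the hierarchical RLWM-LBA model
#'
#' Group-mean priors are normal on the unconstrained scale; group standard
#' deviations have Exponential(0.1) priors and subject-level deviations are
#' standard normal. In the desk-scale empirical-Bayes MAP mode each subject's
#' unconstrained parameters receive a `Normal(mean, map_sd)` prior centred at
#' the group-mean prior locations; `beta_slope` has a `Normal(0, 1)` prior on
#' its natural scale.
#'
#' @param mean Named numeric vector of prior means on the unconstrained scale.
#' @param sd Named numeric vector of prior sds for the group means.
#' @param sd_rate Rate of the Exponential prior on group sds.
#' @param map_sd Per-subject prior sd used by the MAP mode.
#' @param beta_slope_sd Prior sd of the CPP-slope coefficient.
#' @return Object of class `rlwm_priors`.
#' @export
rlwm_priors <- function(mean = c(alpha_rl = -3, bias = -1, phi = -1, rho = 2,
                                 capacity = 3, A = 2, k = 1, tau = -1, eta = 3),
                        sd = stats::setNames(rep(3, 9), names(mean)),
                        sd_rate = 0.1, map_sd = 3, beta_slope_sd = 1) {
  stopifnot(identical(names(mean), PARAM_NAMES[1:9]))
  structure(list(mean = mean, sd = sd, sd_rate = sd_rate,
                 map_sd = map_sd, beta_slope_sd = beta_slope_sd),
            class = "rlwm_priors")
}
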