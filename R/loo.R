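# Generalized Pareto fit to tail exceedances (Zhang & Stephens 2009 profile
# posterior), used to smooth importance weights.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior <- 3
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior * xstar)
  kfun <- vapply(theta, function(th) mean(log1p(-th * x)), 0)
  l_theta <- n * (log(-theta / kfun) + kfun - 1)
  w <- exp(l_theta - max(l_theta))
  w <- w / sum(w)
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  list(k = -k, sigma = sigma)
}

# Quantile function of the GPD with shape k (xi) and scale sigma, support > 0.
gpd_quantile <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smoothed importance-sampling LOO from a draws x observations matrix
# of pointwise log-likelihoods. `logw` holds per-draw log importance weights
# of the draws against the posterior (zero when the draws are posterior
# draws); the LOO ratios for observation i are then w_s / p(y_i | theta_s).
# Returns pointwise elpd and khat diagnostics.
psis_loo_pointwise <- function(ll, logw = NULL) {
  S <- nrow(ll)
  n <- ncol(ll)
  if (is.null(logw)) logw <- matrix(0, S, n)
  elpd <- numeric(n)
  khat <- numeric(n)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  for (i in seq_len(n)) {
    l <- ll[, i]
    lw <- logw[, i] - l
    lw <- lw - max(lw)
    if (M >= 5 && stats::sd(lw) > 0) {
      ord <- order(lw)
      tail_ids <- ord[(S - M + 1L):S]
      cut <- exp(lw[ord[S - M]])
      exceed <- exp(lw[tail_ids]) - cut
      if (all(exceed >= 0) && max(exceed) > 0) {
        fit <- tryCatch(gpd_fit(exceed[exceed > 0]), error = function(e) NULL)
        if (!is.null(fit) && is.finite(fit$k) && is.finite(fit$sigma) &&
            fit$sigma > 0) {
          q <- gpd_quantile((seq_len(M) - 0.5) / M, fit$k, fit$sigma) + cut
          q <- pmin(q, max(exp(lw)))
          lw[tail_ids[order(lw[tail_ids])]] <- log(q)
          khat[i] <- fit$k
        }
      }
    }
    lw <- lw - max(lw)
    # elpd_i = log( sum w * p ) - log( sum w ), in log space
    elpd[i] <- log_sum_exp(lw + l) - log_sum_exp(lw)
  }
  list(elpd = elpd, khat = khat)
}

# WAIC-style pointwise elpd: importance-weighted lpd minus a weighted
# pointwise variance penalty.
waic_pointwise <- function(ll, logw = NULL) {
  S <- nrow(ll)
  if (is.null(logw)) logw <- matrix(0, S, ncol(ll))
  elpd <- vapply(seq_len(ncol(ll)), function(i) {
    lw <- logw[, i] - max(logw[, i])
    w <- exp(lw) / sum(exp(lw))
    lpd <- log_sum_exp(lw + ll[, i]) - log_sum_exp(lw)
    m <- sum(w * ll[, i])
    p <- sum(w * (ll[, i] - m)^2)
    lpd - p
  }, 0)
  list(elpd = elpd, khat = rep(NA_real_, ncol(ll)))
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Compare two fitted models by expected log predictive density
#'
#' Computes pointwise leave-one-out expected log predictive density for each
#' fit from its pointwise log-likelihood draws — by Pareto-smoothed importance
#' sampling (PSIS-LOO) or a WAIC-style penalty — and reports the ELPD
#' difference `better - worse` with its standard error
#' `se = sqrt(n * var(pointwise differences))`. For MAP-mode fits the draws
#' are Laplace approximations, which the output records.
#'
#' @param fit_a,fit_b Two [rlwm_lba()] fits of the same trials.
#' @param method `"psis"` (default) or `"waic"`.
#' @return Object of class `rlwm_elpd_comparison` with fields `elpd` (per
#'   model), `elpd_diff`, `se_diff`, `better`, `pointwise_diff`, `khat`.
#' @export
compare_elpd <- function(fit_a, fit_b, method = c("psis", "waic")) {
  method <- match.arg(method)
  if (fit_a$n_trials != fit_b$n_trials)
    stop("fits must be of identical trial sets")
  f <- if (method == "psis") psis_loo_pointwise else waic_pointwise
  a <- f(fit_a$pointwise_loglik)
  b <- f(fit_b$pointwise_loglik)
  d <- a$elpd - b$elpd
  better <- if (sum(d) >= 0) fit_a$model_tag else fit_b$model_tag
  dd <- if (sum(d) >= 0) d else -d
  n <- length(d)
  structure(list(
    elpd = c(stats::setNames(sum(a$elpd), fit_a$model_tag),
             stats::setNames(sum(b$elpd), fit_b$model_tag)),
    elpd_diff = sum(dd),
    se_diff = sqrt(n * stats::var(dd)),
    better = better, pointwise_diff = dd, n = n,
    khat = c(a = suppressWarnings(max(a$khat, na.rm = TRUE)),
             b = suppressWarnings(max(b$khat, na.rm = TRUE))),
    method = method,
    note = "pointwise draws are Laplace approximations under MAP mode"
  ), class = "rlwm_elpd_comparison")
}

#' @export
print.rlwm_elpd_comparison <- function(x, ...) {
  cat("ELPD model comparison (", x$method, ")\n", sep = "")
  for (nm in names(x$elpd))
    cat(sprintf("  elpd[%s] = %.1f\n", nm, x$elpd[[nm]]))
  cat(sprintf("  elpd_diff (better - worse) = %.1f, se = %.1f (better: %s)\n",
              x$elpd_diff, x$se_diff, x$better))
  invisible(x)
}
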