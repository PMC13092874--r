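# Encode one subject's trials for the C++ replay kernel: consecutive block
# ids, within-block stimulus indices, observed actions/rewards/RTs.
# Trials must be in chronological order within the subject.
encode_trials <- function(trials) {
  blocks <- unique(trials$block)
  block_id <- match(trials$block, blocks)
  stim_idx <- integer(nrow(trials))
  for (b in seq_along(blocks)) {
    sel <- block_id == b
    stim_idx[sel] <- match(trials$stimulus[sel], unique(trials$stimulus[sel]))
  }
  if (any(stim_idx > trials$set_size))
    stop("more distinct stimuli than set_size within a block")
  list(block = as.integer(block_id), stim = as.integer(stim_idx),
       action = as.integer(trials$action), reward = as.integer(trials$reward),
       rt = as.numeric(trials$rt), set_size = as.integer(trials$set_size))
}

#' Z-score CPP slopes within subject
#'
#' @param slopes Numeric vector of trial-wise CPP slopes.
#' @param subject Subject id per trial.
#' @return Numeric vector of within-subject z-scores, with the per-subject
#'   means and sds attached as attribute `"scaling"`.
#' @export
standardize_slopes <- function(slopes, subject) {
  stopifnot(length(slopes) == length(subject))
  mu <- tapply(slopes, subject, mean)
  sdv <- tapply(slopes, subject, stats::sd)
  z <- (slopes - mu[as.character(subject)]) / sdv[as.character(subject)]
  attr(z, "scaling") <- data.frame(subject = names(mu), mean = as.numeric(mu),
                                   sd = as.numeric(sdv))
  z
}

#' Pointwise log-likelihood of one subject's trials
#'
#' Replays the agent forward through the subject's trials (policy, prior
#' entropy, drift rates with `eta` or the slope-informed `eta_t`, LBA race
#' density, value update, WM decay) and returns one log-density per trial.
#' With `slopes = NULL` (or `beta_slope = 0`) this is the baseline model.
#'
#' @param trials One subject's trial data.frame in chronological order, with
#'   columns `block, set_size, stimulus, action, reward, rt`.
#' @param theta Named parameter vector on the constrained scale (see
#'   [constrain_params()]); `beta_slope` may be omitted.
#' @param slopes Optional per-trial standardized CPP slopes (aligned with
#'   `trials`).
#' @param beta_rl,beta_wm Fixed softmax sensitivities.
#' @param s Fixed drift-rate sd.
#' @param eps_h Entropy floor in bits.
#' @param eta_min Floor on the trial-wise drift scaling.
#' @return Numeric vector of per-trial log-likelihoods.
#' @export
subject_loglik <- function(trials, theta, slopes = NULL,
                           beta_rl = 50, beta_wm = 50, s = 1,
                           eps_h = 1e-6, eta_min = 0.01) {
  if (length(theta) == 9L) theta <- c(theta, beta_slope = 0)
  theta <- theta[PARAM_NAMES]
  enc <- encode_trials(trials)
  if (is.null(slopes)) slopes <- numeric(nrow(trials))
  if (length(slopes) != nrow(trials)) stop("slope vector misaligned with trials")
  rlwm_lba_loglik_cpp(as.numeric(theta), enc$block, enc$stim, enc$action,
                      enc$reward, enc$rt, enc$set_size, as.numeric(slopes),
                      beta_rl, beta_wm, s, eps_h, eta_min)
}

# MAP fit of one subject with multi-start gradient-based optimization and a
# Laplace approximation at the optimum. Returns MAP, covariance, draws.
# `center`/`scale` give the prior location and sd on the unconstrained scale
# (the fixed prior locations in stage 1, the estimated group in stage 2);
# `extra_starts` seeds additional optimizer starts (e.g. the stage-1 MAP).
fit_subject <- function(trials, slopes, priors, neural, n_starts, n_draws,
                        seed, center = NULL, scale = NULL,
                        extra_starts = NULL, beta_fixed = NULL,
                        beta_rl = 50, beta_wm = 50,
                        s = 1, eps_h = 1e-6, eta_min = 0.01) {
  enc <- if (nrow(trials) > 0L) encode_trials(trials) else NULL
  sl <- if (is.null(slopes)) numeric(nrow(trials)) else as.numeric(slopes)
  free_beta <- neural && is.null(beta_fixed)
  tail_beta <- if (free_beta) NULL else if (neural) beta_fixed else 0
  npar <- if (free_beta) 10L else 9L
  if (is.null(center)) center <- c(priors$mean, if (free_beta) 0)
  if (is.null(scale)) scale <- c(rep(priors$map_sd, 9),
                                 if (free_beta) priors$beta_slope_sd)
  negpost <- function(x) {
    xx <- if (free_beta) x else c(x, tail_beta)
    ll <- if (is.null(enc)) 0 else
      sum(rlwm_lba_loglik_cpp(as.numeric(constrain_params(xx)),
                              enc$block, enc$stim, enc$action, enc$reward,
                              enc$rt, enc$set_size, sl,
                              beta_rl, beta_wm, s, eps_h, eta_min))
    -(ll + sum(stats::dnorm(x, center, scale, log = TRUE)))
  }
  local_rng(seed, "fit-subject")
  x0 <- center
  starts <- rbind(x0)
  if (n_starts > 1L)
    starts <- rbind(starts,
                    matrix(x0, n_starts - 1L, npar, byrow = TRUE) +
                      matrix(stats::rnorm((n_starts - 1L) * npar, 0, 1),
                             n_starts - 1L))
  if (!is.null(extra_starts)) starts <- rbind(extra_starts, starts)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    opt <- tryCatch(
      stats::nlminb(starts[i, ], negpost,
                    control = list(rel.tol = 1e-8, iter.max = 400)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  if (is.null(best)) stop("all optimizer starts failed")
  map <- best$par
  H <- tryCatch(stats::optimHess(map, negpost), error = function(e) NULL)
  cov <- laplace_cov(H, npar)
  # Posterior draws by short adaptive random-walk Metropolis started at the
  # MAP, with the Laplace covariance shaping the proposal; the step scale is
  # tuned toward the standard 0.234 acceptance target during burn-in.
  mcmc <- rw_metropolis(negpost, map, cov, n_draws, burn = 600L, thin = 10L)
  draws <- mcmc$draws
  if (!free_beta) {
    map <- c(map, tail_beta)
    draws <- cbind(draws, tail_beta)
  }
  colnames(draws) <- PARAM_NAMES
  list(map_unconstrained = stats::setNames(map, PARAM_NAMES),
       map_constrained = constrain_params(map),
       vcov = cov, draws = draws, accept_rate = mcmc$accept_rate,
       prior_center = center, prior_scale = scale, npar = npar,
       objective = best$objective, convergence = best$convergence,
       message = best$message)
}

# Invert a numerical Hessian into a Laplace covariance, flooring eigenvalues
# so the result is positive definite even when some directions are flat.
# The floor matches the weakest prior curvature, so no direction can have a
# posterior sd wildly beyond the prior scale.
laplace_cov <- function(H, npar) {
  if (is.null(H) || any(!is.finite(H)))
    return(diag(1e-1, npar))
  eig <- eigen((H + t(H)) / 2, symmetric = TRUE)
  vals <- pmax(eig$values, 0.1)
  eig$vectors %*% diag(1 / vals, npar) %*% t(eig$vectors)
}

draw_mvnorm <- function(n, mean, cov) {
  L <- chol(cov)
  z <- matrix(stats::rnorm(n * length(mean)), n)
  pmin(pmax(sweep(z %*% L, 2L, mean, "+"), -20), 20)
}

# Adaptive random-walk Metropolis; returns `n_keep` thinned draws.
rw_metropolis <- function(neglp, x0, cov, n_keep, burn = 400L, thin = 8L) {
  npar <- length(x0)
  L <- chol((cov + t(cov)) / 2)
  scale <- 2.38 / sqrt(npar)
  x <- x0
  lp <- -neglp(x)
  n_iter <- burn + thin * n_keep
  kept <- matrix(NA_real_, n_keep, npar)
  acc <- 0L
  ki <- 0L
  for (t in seq_len(n_iter)) {
    prop <- x + scale * drop(stats::rnorm(npar) %*% L)
    lp_p <- tryCatch(-neglp(prop), error = function(e) -Inf)
    if (is.finite(lp_p) && log(stats::runif(1)) < lp_p - lp) {
      x <- prop; lp <- lp_p; acc <- acc + 1L
    }
    if (t <= burn)
      scale <- scale * exp(0.05 * ((acc / t) - 0.234))
    if (t > burn && (t - burn) %% thin == 0L) {
      ki <- ki + 1L
      kept[ki, ] <- x
    }
  }
  list(draws = kept, accept_rate = acc / n_iter)
}

#' Fit the RLWM-LBA model
#'
#' Fits the hybrid reinforcement-learning/working-memory accumulator model to
#' trial-level choice and RT data. Each subject's nine cognitive and race
#' parameters (learning rate, feedback bias, WM decay, WM propensity,
#' capacity, start-point range, relative threshold, non-decision time, drift
#' scaling) are estimated by MAP optimization on the unconstrained scale under
#' the group priors (empirical-Bayes desk mode), with a Laplace approximation
#' supplying posterior draws. Supplying per-trial CPP slopes fits the neurally
#' informed variant, adding the coefficient `beta_slope` through which the
#' standardized slope modulates the trial-wise drift scaling
#' `eta_t = eta + z(slope) * beta_slope`. Group-level posterior summaries are
#' obtained by precision-weighted random-effects pooling of the subject
#' posteriors.
#'
#' @param trials Trial data.frame (chronological within subject) with columns
#'   `subject, block, set_size, stimulus, action, reward, rt`.
#' @param slopes Optional numeric vector of trial-wise CPP slopes aligned with
#'   `trials`; standardized within subject before entering the model. When
#'   given, the neurally informed model is fitted.
#' @param priors A [rlwm_priors()] object.
#' @param mode Approximation mode; `"map"` (per-subject MAP + Laplace draws)
#'   is the supported desk-scale mode.
#' @param n_starts Number of optimizer starts per subject.
#' @param n_draws Number of Laplace posterior draws per subject.
#' @param seed Integer seed (drives starts and draws).
#' @param ... Fixed model constants passed to the likelihood
#'   (`beta_rl`, `beta_wm`, `s`, `eps_h`, `eta_min`).
#' @return An object of class `rlwm_lba_fit`; see [summary.rlwm_lba_fit()].
#' @export
rlwm_lba <- function(trials, slopes = NULL, priors = rlwm_priors(),
                     mode = "map", n_starts = 5L, n_draws = 100L,
                     seed = 1L, ...) {
  mode <- match.arg(mode, "map")
  neural <- !is.null(slopes)
  if (neural && length(slopes) != nrow(trials))
    stop("slopes must align with trials")
  sl_z <- if (neural) standardize_slopes(slopes, trials$subject) else NULL
  subjects <- unique(trials$subject)
  idx_by_subj <- split(seq_len(nrow(trials)), factor(trials$subject, subjects))
  fits <- vector("list", length(subjects))
  names(fits) <- as.character(subjects)
  pointwise <- matrix(NA_real_, n_draws, nrow(trials))
  loglik_map <- numeric(nrow(trials))
  npar <- if (neural) 10L else 9L
  # Stage 1: independent MAPs under the weak group-location priors.
  stage1 <- matrix(NA_real_, length(subjects), npar)
  stage1_var <- matrix(NA_real_, length(subjects), npar)
  for (j in seq_along(subjects)) {
    idx <- idx_by_subj[[j]]
    zj <- if (neural) sl_z[idx] else NULL
    f1 <- fit_subject(trials[idx, , drop = FALSE], zj, priors, neural,
                      n_starts, n_draws = 2L, seed = seed + 1000L * j, ...)
    stage1[j, ] <- f1$map_unconstrained[seq_len(npar)]
    stage1_var[j, ] <- pmax(diag(f1$vcov), 1e-6)
  }
  # Empirical-Bayes group distribution on the unconstrained scale:
  # precision-weighted random-effects pooling of the stage-1 estimates, so
  # subjects whose data barely constrain a parameter (large Laplace variance)
  # do not drag the group location toward the stage-1 prior. The estimated
  # between-subject sd tau becomes the stage-2 shrinkage scale.
  g_mean <- numeric(npar)
  g_sd <- numeric(npar)
  beta_pool <- NULL
  for (p in seq_len(npar)) {
    re <- tryCatch(
      suppressWarnings(
        metafor::rma.uni(yi = stage1[, p], vi = stage1_var[, p],
                         method = "DL")),
      error = function(e) NULL)
    if (is.null(re)) {
      g_mean[p] <- mean(stage1[, p])
      g_sd[p] <- stats::sd(stage1[, p])
      if (neural && p == 10L) {
        se <- g_sd[p] / sqrt(length(subjects))
        beta_pool <- data.frame(parameter = "beta_slope", mean = g_mean[p],
                                se = se, ci_lo = g_mean[p] - 1.96 * se,
                                ci_hi = g_mean[p] + 1.96 * se)
      }
    } else {
      g_mean[p] <- as.numeric(re$beta)
      g_sd[p] <- sqrt(re$tau2)
      if (neural && p == 10L)
        beta_pool <- data.frame(parameter = "beta_slope",
                                mean = as.numeric(re$beta), se = re$se,
                                ci_lo = re$ci.lb, ci_hi = re$ci.ub)
    }
  }
  g_sd <- pmin(pmax(g_sd, 0.1), 3)
  if (length(subjects) < 3L) {
    g_mean <- c(priors$mean, if (neural) 0)
    g_sd <- c(rep(priors$map_sd, 9), if (neural) priors$beta_slope_sd)
    if (neural)
      beta_pool <- data.frame(parameter = "beta_slope",
                              mean = mean(stage1[, 10]),
                              se = priors$beta_slope_sd,
                              ci_lo = NA_real_, ci_hi = NA_real_)
  }
  # The slope coefficient is a single group-level parameter (as in the
  # hierarchical model): fix it at its pooled estimate for stage 2, so the
  # neural model carries one effective extra parameter overall rather than
  # one per subject.
  beta_hat <- if (neural) g_mean[10] else NULL
  # Stage 2: refit every subject under the estimated group prior
  # (the subject-level conditional of the hierarchical model).
  for (j in seq_along(subjects)) {
    idx <- idx_by_subj[[j]]
    tr <- trials[idx, , drop = FALSE]
    zj <- if (neural) sl_z[idx] else NULL
    fits[[j]] <- fit_subject(tr, zj, priors, neural, n_starts = 2L, n_draws,
                             seed = seed + 1000L * j + 1L,
                             center = g_mean[1:9], scale = g_sd[1:9],
                             beta_fixed = beta_hat,
                             extra_starts = stage1[j, 1:9, drop = FALSE], ...)
    loglik_map[idx] <- subject_loglik(tr, fits[[j]]$map_constrained, zj, ...)
    cdraws <- t(apply(fits[[j]]$draws, 1L, constrain_params))
    for (d in seq_len(n_draws)) {
      pointwise[d, idx] <- subject_loglik(tr, cdraws[d, ], zj, ...)
    }
    fits[[j]]$post_mean <- colMeans(cdraws)
    fits[[j]]$post_var <- apply(cdraws, 2L, stats::var)
  }
  grp <- group_summary(fits, neural = FALSE)
  if (neural) grp <- rbind(grp, beta_pool)
  rownames(grp) <- NULL
  structure(list(
    subject_fits = fits, group = grp, pointwise_loglik = pointwise,
    loglik_map = loglik_map, model_tag = if (neural) "neural" else "baseline",
    priors = priors, mode = mode, seed = seed,
    n_trials = nrow(trials), subjects = subjects,
    slope_scaling = if (neural) attr(sl_z, "scaling") else NULL,
    slopes_z = sl_z,
    trials = trials, call = match.call()
  ), class = "rlwm_lba_fit")
}

# Precision-weighted random-effects pooling (DerSimonian-Laird via metafor)
# of per-subject posterior means on the constrained scale.
group_summary <- function(fits, neural) {
  pars <- if (neural) PARAM_NAMES else PARAM_NAMES[1:9]
  rows <- lapply(pars, function(p) {
    est <- vapply(fits, function(f) f$post_mean[[p]], 0)
    vi <- vapply(fits, function(f) f$post_var[[p]], 0)
    vi <- pmax(vi, 1e-10)
    re <- tryCatch(
      suppressWarnings(metafor::rma.uni(yi = est, vi = vi, method = "DL")),
      error = function(e) NULL)
    if (is.null(re)) {
      m <- mean(est); se <- stats::sd(est) / sqrt(length(est))
      data.frame(parameter = p, mean = m, se = se,
                 ci_lo = m - 1.96 * se, ci_hi = m + 1.96 * se)
    } else {
      data.frame(parameter = p, mean = as.numeric(re$beta),
                 se = re$se, ci_lo = re$ci.lb, ci_hi = re$ci.ub)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
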