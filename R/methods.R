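#' @export
print.rlwm_lba_fit <- function(x, ...) {
  cat(sprintf("RLWM-LBA fit (%s model, %s mode)\n", x$model_tag, x$mode))
  cat(sprintf("  %d subjects, %d trials, log-likelihood at MAP %.1f\n",
              length(x$subjects), x$n_trials, sum(x$loglik_map)))
  cat("  group posterior means (constrained scale):\n")
  g <- x$group
  cat(paste0("    ", g$parameter, " = ", signif(g$mean, 3), collapse = "\n"),
      "\n")
  invisible(x)
}

#' Summarize a fitted RLWM-LBA model
#'
#' @param object An [rlwm_lba()] fit.
#' @param ... Unused.
#' @return List with the group-level posterior summary table, the matrix of
#'   per-subject MAP estimates (constrained scale) and convergence codes.
#' @export
summary.rlwm_lba_fit <- function(object, ...) {
  maps <- t(vapply(object$subject_fits, function(f) f$map_constrained,
                   numeric(10)))
  out <- list(group = object$group, subject_map = maps,
              model_tag = object$model_tag,
              convergence = vapply(object$subject_fits,
                                   function(f) f$convergence, 0L),
              n_trials = object$n_trials)
  class(out) <- "summary.rlwm_lba_fit"
  out
}

#' @export
print.summary.rlwm_lba_fit <- function(x, ...) {
  cat(sprintf("RLWM-LBA %s model: %d subjects, %d trials\n", x$model_tag,
              nrow(x$subject_map), x$n_trials))
  cat("Group posterior summary (random-effects pooling of subject posteriors):\n")
  print(x$group, row.names = FALSE, digits = 3)
  if (any(x$convergence != 0L))
    cat(sprintf("note: %d subject(s) with nonzero optimizer convergence code\n",
                sum(x$convergence != 0L)))
  invisible(x)
}

#' @export
coef.rlwm_lba_fit <- function(object, ...) {
  stats::setNames(object$group$mean, object$group$parameter)
}

#' @export
logLik.rlwm_lba_fit <- function(object, ...) {
  npar <- length(object$subject_fits) * if (object$model_tag == "neural") 10 else 9
  structure(sum(object$loglik_map), df = npar, nobs = object$n_trials,
            class = "logLik")
}

#' Replay fitted latent trial variables
#'
#' Replays each subject's trials under their MAP parameters and returns the
#' model-inferred latent variables used as EEG predictors: the mixed policy
#' probability of the chosen action, the prior policy entropy, the drift rate
#' of the chosen accumulator, the pre-choice Q values of both modules and the
#' trial-wise drift scaling.
#'
#' @param object An [rlwm_lba()] fit.
#' @param ... Unused.
#' @return data.frame with one row per fitted trial, aligned with the trials
#'   the model was fitted to.
#' @export
predict.rlwm_lba_fit <- function(object, ...) {
  trials <- object$trials
  out <- vector("list", length(object$subjects))
  idx <- split(seq_len(nrow(trials)), factor(trials$subject, object$subjects))
  for (j in seq_along(object$subjects)) {
    tr <- trials[idx[[j]], , drop = FALSE]
    th <- object$subject_fits[[j]]$map_constrained
    zj <- if (!is.null(object$slopes_z)) object$slopes_z[idx[[j]]] else NULL
    out[[j]] <- replay_latents(tr, th, zj)
  }
  res <- do.call(rbind, out)[order(unlist(idx)), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Pure-R forward replay returning latent trial variables at fixed parameters.
replay_latents <- function(trials, theta, slopes_z = NULL,
                           beta_rl = 50, beta_wm = 50,
                           eps_h = 1e-6, eta_min = 0.01) {
  agent <- agent_params(theta[["alpha_rl"]], theta[["bias"]], theta[["phi"]],
                        theta[["rho"]], theta[["capacity"]],
                        beta_rl = beta_rl, beta_wm = beta_wm)
  if (is.null(slopes_z)) slopes_z <- numeric(nrow(trials))
  beta_slope <- if ("beta_slope" %in% names(theta)) theta[["beta_slope"]] else 0
  n <- nrow(trials)
  out <- data.frame(pi_chosen = numeric(n), h_prior = numeric(n),
                    drift_chosen = numeric(n), eta_t = numeric(n),
                    q_rl_chosen = numeric(n), q_wm_chosen = numeric(n))
  state <- NULL
  cur_block <- NULL
  stim_map <- NULL
  for (i in seq_len(n)) {
    if (is.null(cur_block) || trials$block[i] != cur_block) {
      cur_block <- trials$block[i]
      state <- agent_state(trials$set_size[i], agent)
      stim_map <- character(0)
    }
    s <- as.character(trials$stimulus[i])
    if (!s %in% stim_map) stim_map <- c(stim_map, s)
    si <- match(s, stim_map)
    pim <- policy_matrix(state, agent)
    mu <- colMeans(pim)
    h <- max(-sum(ifelse(mu > 0, mu * log2(mu), 0)), eps_h)
    a <- trials$action[i]
    eta_t <- max(theta[["eta"]] + beta_slope * slopes_z[i], eta_min)
    out$pi_chosen[i] <- pim[si, a]
    out$h_prior[i] <- h
    out$eta_t[i] <- eta_t
    out$drift_chosen[i] <- eta_t * pim[si, a] / h
    out$q_rl_chosen[i] <- state$q_rl[si, a]
    out$q_wm_chosen[i] <- state$q_wm[si, a]
    r <- trials$reward[i]
    state$q_rl[si, a] <- rl_update(state$q_rl[si, a], r, agent)
    state$q_wm[si, a] <- wm_update(state$q_wm[si, a], r, agent)
    state <- wm_decay(state, agent)
  }
  out
}

#' Crude expected-RT residuals
#'
#' Residual = observed RT minus the ballistic approximation of the expected
#' RT given the chosen accumulator (`tau + (b - A/2) / v_chosen`), a quick
#' diagnostic of RT misfit.
#'
#' @param object An [rlwm_lba()] fit.
#' @param ... Unused.
#' @return Numeric vector of residuals in seconds.
#' @export
residuals.rlwm_lba_fit <- function(object, ...) {
  lat <- predict(object)
  trials <- object$trials
  res <- numeric(nrow(trials))
  idx <- split(seq_len(nrow(trials)), factor(trials$subject, object$subjects))
  for (j in seq_along(object$subjects)) {
    th <- object$subject_fits[[j]]$map_constrained
    b <- th[["A"]] + th[["k"]]
    i <- idx[[j]]
    res[i] <- trials$rt[i] -
      (th[["tau"]] + (b - th[["A"]] / 2) / pmax(lat$drift_chosen[i], 1e-6))
  }
  res
}

#' Posterior-predictive simulation from a fit
#'
#' Re-administers each fitted subject's blocks (set sizes and correct-action
#' maps reconstructed from the fitted trials) with choices and RTs generated
#' under the subject's MAP parameters.
#'
#' @param object An [rlwm_lba()] fit.
#' @param nsim Number of replicate datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A trial data.frame (one replicate) or a list of them.
#' @export
simulate.rlwm_lba_fit <- function(object, nsim = 1, seed = 1L, ...) {
  trials <- object$trials
  reps <- vector("list", nsim)
  for (r in seq_len(nsim)) {
    tabs <- list()
    for (j in seq_along(object$subjects)) {
      sid <- object$subjects[j]
      tr <- trials[trials$subject == sid, , drop = FALSE]
      th <- object$subject_fits[[j]]$map_constrained
      agent <- agent_params(th[["alpha_rl"]], th[["bias"]], th[["phi"]],
                            th[["rho"]], th[["capacity"]])
      lba <- lba_params(th[["A"]], th[["k"]], th[["tau"]], th[["eta"]])
      blocks <- lapply(unique(tr$block), function(b) {
        tb <- tr[tr$block == b, ]
        stims <- unique(tb$stimulus)
        block_spec(b, tb$set_size[1], stims,
                   tb$correct_action[match(stims, tb$stimulus)])
      })
      local_rng(seed + 131L * r + j, "posterior-predictive")
      tabs[[j]] <- sim_subject(blocks, agent, lba, sid, beta_slope = 0,
                               lambda = 0, slope_base = 0, slope_scale = 0)
    }
    reps[[r]] <- do.call(rbind, tabs)
  }
  if (nsim == 1) reps[[1]] else reps
}

#' Plot observed vs posterior-predictive learning curves
#'
#' Mean accuracy by presentation index, split by set size, for the fitted
#' trials (solid) and one posterior-predictive replicate (dashed).
#'
#' @param x An [rlwm_lba()] fit.
#' @param seed Seed for the predictive replicate.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.rlwm_lba_fit <- function(x, seed = 1L, ...) {
  curve_of <- function(tr) {
    tapply(tr$reward, list(tr$presentation_index, tr$set_size), mean)
  }
  obs <- curve_of(x$trials)
  sim <- curve_of(simulate(x, seed = seed))
  graphics::matplot(as.integer(rownames(obs)), obs, type = "l", lty = 1,
                    xlab = "presentation index", ylab = "accuracy",
                    ylim = c(0, 1), ...)
  graphics::matlines(as.integer(rownames(sim)), sim, lty = 2)
  graphics::legend("bottomright", legend = colnames(obs), lty = 1,
                   col = seq_len(ncol(obs)), title = "set size", bty = "n")
  invisible(x)
}
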