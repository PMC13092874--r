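#' Configuration of the synthetic-data generator
#'
#' Group-level parameter means and standard deviations are specified on the
#' unconstrained scale and mapped through the same transforms as the fitting
#' routines ([constrain_params()]). The defaults describe a mid-range adult
#' learner population: learning rate around 0.05, moderate neglect of
#' negative feedback, WM decay around 0.14, strong WM reliance, capacity
#' around 4, and race parameters giving response times between roughly 0.4
#' and 3 seconds that shorten as learning concentrates the policy.
#'
#' The trial-wise CPP slope is generated as
#' `slope = slope_base + slope_scale * zeta` (microvolts/ms) with
#' `zeta = slope_drift_cor * z(drift) + sqrt(1 - slope_drift_cor^2) * noise`,
#' where `z(drift)` standardizes the leading baseline drift rate of the trial
#' within subject; `zeta` then modulates the drift scaling as
#' `eta_t = eta + beta_slope_true * zeta`. Setting `slope_drift_cor = 1`
#' makes the slope a deterministic function of drift;
#' `beta_slope_true = 0` removes the neural coupling while keeping the
#' slope-drift correlation.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param group_mean,group_sd Named 9-vectors (unconstrained scale) for
#'   `alpha_rl, bias, phi, rho, capacity, A, k, tau, eta`.
#' @param beta_slope_true Generating coefficient linking the standardized CPP
#'   slope to the trial-wise drift scaling.
#' @param slope_drift_cor Correlation between the latent slope and the
#'   standardized leading drift rate.
#' @param slope_base,slope_scale Location and scale mapping the latent
#'   standardized slope to microvolts/ms.
#' @param design A [design_spec()].
#' @param eeg List of EEG generation settings; see Details in
#'   [simulate_eeg()].
#' @param seed Base seed.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(
    n_subjects = 20L,
    group_mean = c(alpha_rl = -1.9, bias = -0.5, phi = -1.1, rho = 1.0,
                   capacity = 0.5, A = -0.3, k = 0, tau = -0.8, eta = 1.1),
    group_sd = c(alpha_rl = 0.5, bias = 0.7, phi = 0.6, rho = 0.8,
                 capacity = 1.0, A = 0.4, k = 0.4, tau = 0.35, eta = 0.5),
    beta_slope_true = 0.094,
    slope_drift_cor = 0.8,
    slope_base = 0.05, slope_scale = 0.045,
    design = design_spec(),
    eeg = list(),
    seed = 1L) {
  stopifnot(identical(names(group_mean), PARAM_NAMES[1:9]),
            identical(names(group_sd), PARAM_NAMES[1:9]))
  if (any(group_sd < 0)) stop("group sds must be non-negative")
  eeg_defaults <- list(
    n_channels = 64L, sampling_rate = 512, window = c(-0.7, 0.7),
    cpp_gain = 1, cpp_decay = 0.2, cpp_max_buildup = 0.6,
    q_effect = 3, delay_effect = 2, setsize_effect = 3,
    q_center = "FCz", delay_center = "FCz", setsize_center = "Pz",
    cpp_center = "CPz", comp_widths = c(q = 0.05, setsize = 0.06),
    comp_latencies = c(q = 0.3, setsize = 0.54),
    spatial_sigma = 0.35, noise_ar = 0.95, noise_sd = 5)
  eeg <- utils::modifyList(eeg_defaults, eeg)
  structure(list(n_subjects = as.integer(n_subjects),
                 group_mean = group_mean, group_sd = group_sd,
                 beta_slope_true = beta_slope_true,
                 slope_drift_cor = slope_drift_cor,
                 slope_base = slope_base, slope_scale = slope_scale,
                 design = design, eeg = eeg, seed = as.integer(seed)),
            class = "generator_config")
}

#' Sample subject-level parameters from the group distribution
#'
#' Unconstrained draws `Normal(group_mean, group_sd)` per subject, mapped
#' through [constrain_params()] — mirroring the hierarchy the fitting
#' routines assume.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed (defaults to the config's).
#' @return List with `unconstrained` (subjects x 9 matrix), `constrained`
#'   (data.frame), and `params` (per-subject list of `agent` = [agent_params()]
#'   and `lba` = [lba_params()]).
#' @export
sample_subject_params <- function(config, seed = config$seed) {
  local_rng(seed, "subject-params")
  n <- config$n_subjects
  x <- matrix(stats::rnorm(n * 9L, rep(config$group_mean, each = n),
                           rep(config$group_sd, each = n)), n)
  colnames(x) <- PARAM_NAMES[1:9]
  con <- t(apply(x, 1L, function(r) constrain_params(r)[1:9]))
  params <- lapply(seq_len(n), function(i) {
    th <- con[i, ]
    list(agent = agent_params(th[["alpha_rl"]], th[["bias"]], th[["phi"]],
                              th[["rho"]], th[["capacity"]]),
         lba = lba_params(th[["A"]], th[["k"]], th[["tau"]], th[["eta"]]))
  })
  list(unconstrained = x, constrained = as.data.frame(con), params = params)
}

# Simulate one subject through the full design: administer every block with
# the adaptive stopping rule, choices and RTs from the accumulator race.
# `moments` holds the subject's leading-drift mean/sd from a decoupled
# pre-pass; when NULL, drift z-scores are taken as 0 (used by the pre-pass).
sim_subject <- function(blocks, agent, lba, subject, beta_slope, lambda,
                        slope_base, slope_scale, moments = NULL,
                        eps_h = 1e-6, eta_min = 0.01, deadline = 7) {
  lat <- new.env(parent = emptyenv())
  lat$rows <- list()
  out <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    spec <- blocks[[bi]]
    state <- agent_state(spec$set_size, agent)
    last <- new.env(parent = emptyenv())
    responder <- function(stim, trial) {
      si <- match(stim, spec$stimulus_ids)
      pim <- policy_matrix(state, agent)
      mu <- colMeans(pim)
      h <- max(-sum(ifelse(mu > 0, mu * log2(mu), 0)), eps_h)
      pi_s <- pim[si, ]
      d_lead <- lba$eta * max(pi_s) / h
      z0 <- if (is.null(moments)) 0 else (d_lead - moments[1]) / moments[2]
      zeta <- lambda * z0 + sqrt(1 - lambda^2) * stats::rnorm(1L)
      eta_t <- max(lba$eta + beta_slope * zeta, eta_min)
      v <- drift_rates(pi_s, h, eta_t)
      for (try in 1:100) {
        race <- simulate_race(v, lba, n = 1L)
        if (race$rt <= deadline) break
      }
      action <- race$choice
      reward <- as.integer(action == spec$correct_action[[stim]])
      lat$rows[[length(lat$rows) + 1L]] <- data.frame(
        pi_chosen = pi_s[action], h_prior = h, drift_chosen = v$v[action],
        drift_lead = d_lead, eta_t = eta_t,
        q_rl_chosen = state$q_rl[si, action],
        q_wm_chosen = state$q_wm[si, action],
        w_wm = state$w_wm,
        cpp_slope = slope_base + slope_scale * zeta)
      last$rt <- min(race$rt, deadline)
      # learn from feedback, then decay WM
      state$q_rl[si, action] <<- rl_update(state$q_rl[si, action], reward, agent)
      state$q_wm[si, action] <<- wm_update(state$q_wm[si, action], reward, agent)
      state <<- wm_decay(state, agent)
      action
    }
    out[[bi]] <- run_block_impl(spec, responder, subject = subject,
                                rt_fun = function(stim, action) last$rt)
  }
  cbind(do.call(rbind, out), do.call(rbind, lat$rows))
}

#' Simulate behavior for a set of subjects
#'
#' Administers the full adaptive design to each subject, with choices and
#' response times generated by the RLWM policy feeding the accumulator race.
#' A decoupled pre-pass per subject calibrates the standardization of the
#' leading drift rate used to generate trial-wise CPP slopes (see
#' [generator_config()]); the main pass couples the slope to the drift
#' scaling through `beta_slope_true`. The delay covariate and the EEG
#' inclusion flag are appended.
#'
#' @param config A [generator_config()].
#' @param subject_params Optional result of [sample_subject_params()];
#'   sampled from the config when omitted.
#' @param seed Integer seed.
#' @return Trial data.frame with task columns (`subject, block, set_size,
#'   stimulus, presentation_index, action, correct_action, reward, rt, delay,
#'   included_in_eeg`) and latent columns (`pi_chosen, h_prior, drift_chosen,
#'   drift_lead, eta_t, q_rl_chosen, q_wm_chosen, w_wm, cpp_slope`).
#' @export
simulate_behavior <- function(config, subject_params = NULL,
                              seed = config$seed) {
  if (is.null(subject_params))
    subject_params <- sample_subject_params(config, seed)
  n <- length(subject_params$params)
  tabs <- vector("list", n)
  for (i in seq_len(n)) {
    p <- subject_params$params[[i]]
    sid <- sprintf("s%03d", i)
    blocks <- make_design(config$design, seed = seed + 17L * i)
    # pre-pass without neural coupling: leading-drift moments for z-scoring
    local_rng(seed + 17L * i, "behavior-prepass")
    pre <- sim_subject(blocks, p$agent, p$lba, sid, beta_slope = 0,
                       lambda = 0, slope_base = config$slope_base,
                       slope_scale = config$slope_scale, moments = NULL)
    m <- c(mean(pre$drift_lead), max(stats::sd(pre$drift_lead), 1e-8))
    local_rng(seed + 17L * i, "behavior-main")
    tabs[[i]] <- sim_subject(blocks, p$agent, p$lba, sid,
                             beta_slope = config$beta_slope_true,
                             lambda = config$slope_drift_cor,
                             slope_base = config$slope_base,
                             slope_scale = config$slope_scale, moments = m)
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  eeg_trial_filter(compute_delay(out))
}
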