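# Shared small fixtures, built once per test run and cached.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# A small 4-block dataset with 3 subjects, used by several suites.
small_trials <- function() fixture("small_trials", function() {
  cfg <- generator_config(n_subjects = 3, design = design_spec(4, c(2, 3, 4, 5)))
  simulate_behavior(cfg, seed = 42)
})

small_config <- function() {
  generator_config(n_subjects = 3, design = design_spec(4, c(2, 3, 4, 5)))
}

# Independent R-level replay of the subject log-likelihood, composed from the
# exported module functions; serves as the oracle for the compiled kernel.
replay_loglik_oracle <- function(trials, theta, slopes_z = NULL,
                                 beta_rl = 50, beta_wm = 50,
                                 eps_h = 1e-6, eta_min = 0.01) {
  agent <- agent_params(theta[["alpha_rl"]], theta[["bias"]], theta[["phi"]],
                        theta[["rho"]], theta[["capacity"]],
                        beta_rl = beta_rl, beta_wm = beta_wm)
  lba <- lba_params(theta[["A"]], theta[["k"]], theta[["tau"]], theta[["eta"]])
  beta_slope <- if ("beta_slope" %in% names(theta)) theta[["beta_slope"]] else 0
  if (is.null(slopes_z)) slopes_z <- numeric(nrow(trials))
  ll <- numeric(nrow(trials))
  state <- NULL; cur <- NULL; smap <- character(0)
  for (i in seq_len(nrow(trials))) {
    if (is.null(cur) || trials$block[i] != cur) {
      cur <- trials$block[i]
      state <- agent_state(trials$set_size[i], agent)
      smap <- character(0)
    }
    s <- as.character(trials$stimulus[i])
    if (!s %in% smap) smap <- c(smap, s)
    si <- match(s, smap)
    h <- prior_entropy(state, agent, eps = eps_h)
    pol <- policy(state, si, agent)
    eta_t <- max(theta[["eta"]] + beta_slope * slopes_z[i], eta_min)
    v <- drift_rates(pol$pi, h, eta_t)
    ll[i] <- trial_loglik(trials$rt[i], trials$action[i], v, lba)
    a <- trials$action[i]; r <- trials$reward[i]
    state$q_rl[si, a] <- rl_update(state$q_rl[si, a], r, agent)
    state$q_wm[si, a] <- wm_update(state$q_wm[si, a], r, agent)
    state <- wm_decay(state, agent)
  }
  ll
}
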