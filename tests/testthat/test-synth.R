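# Hand-built subject parameter sets for boundary scenarios.
manual_params <- function(alpha, bias, phi, rho, capacity, A, k, tau, eta) {
  list(unconstrained = NULL,
       constrained = data.frame(alpha_rl = alpha, bias = bias, phi = phi,
                                rho = rho, capacity = capacity, A = A, k = k,
                                tau = tau, eta = eta),
       params = list(list(agent = agent_params(alpha, bias, phi, rho, capacity),
                          lba = lba_params(A, k, tau, eta))))
}

test_that("a perfect working-memory learner is flawless from the second presentation", {
  cfg <- generator_config(n_subjects = 1, design = design_spec(2, c(2, 2)),
                          beta_slope_true = 0)
  sp <- manual_params(alpha = 0.05, bias = 0.5, phi = 1e-9, rho = 1 - 1e-9,
                      capacity = 5 - 1e-9, A = 0.3, k = 1, tau = 0.35,
                      eta = 20)
  tr <- simulate_behavior(cfg, subject_params = sp, seed = 2)
  # once a stimulus has been answered correctly, the one-shot WM value and
  # the strong drift make every later presentation of it correct
  for (s in unique(tr$stimulus)) {
    rs <- tr$reward[tr$stimulus == s]
    first_hit <- match(1L, rs)
    if (!is.na(first_hit) && first_hit < length(rs))
      expect_true(all(rs[(first_hit + 1):length(rs)] == 1L))
  }
  # and with only two associations, learning is immediate after presentation 1
  expect_gt(mean(tr$reward[tr$presentation_index >= 3]), 0.95)
})

test_that("an agent without learning stays at chance", {
  cfg <- generator_config(n_subjects = 1, beta_slope_true = 0)
  sp <- manual_params(alpha = 1e-9, bias = 0.5, phi = 0.1, rho = 1e-9,
                      capacity = 3, A = 0.5, k = 1, tau = 0.3, eta = 2)
  tr <- simulate_behavior(cfg, subject_params = sp, seed = 3)
  acc <- mean(tr$reward)
  expect_lt(abs(acc - 1 / 3), 4 * sqrt(1 / 9 * 2 / (3 * nrow(tr))) + 0.02)
})

test_that("behavioral tables carry the documented task and latent columns", {
  tr <- small_trials()
  expect_true(all(c("subject", "block", "set_size", "stimulus",
                    "presentation_index", "action", "correct_action",
                    "reward", "rt", "delay", "included_in_eeg",
                    "pi_chosen", "h_prior", "drift_chosen", "eta_t",
                    "q_rl_chosen", "q_wm_chosen", "cpp_slope") %in% names(tr)))
  expect_true(all(tr$reward == (tr$action == tr$correct_action)))
  expect_true(all(tr$rt > 0 & tr$rt <= 7))
  expect_true(all(tr$h_prior >= 1e-6 & tr$h_prior <= log2(3) + 1e-9))
  # determinism under the seed
  cfg <- small_config()
  expect_identical(simulate_behavior(cfg, seed = 42), tr)
})

test_that("generated CPP slopes track the drift rate within subject", {
  cfg <- generator_config(n_subjects = 3, design = design_spec(4, c(2, 3, 4, 5)))
  tr <- simulate_behavior(cfg, seed = 6)
  for (s in unique(tr$subject)) {
    i <- tr$subject == s & tr$included_in_eeg
    expect_gt(cor(tr$cpp_slope[i], tr$drift_chosen[i]), 0.5)
  }
})

test_that("noiseless EEG yields slopes monotone in the generating buildup", {
  cfg <- generator_config(
    n_subjects = 1, design = design_spec(3, c(2, 3, 4)),
    slope_drift_cor = 1,
    eeg = list(n_channels = 16, sampling_rate = 64, noise_sd = 0,
               q_effect = 0, delay_effect = 0, setsize_effect = 0))
  sp <- manual_params(alpha = 0.03, bias = 0.4, phi = 0.12, rho = 0.85,
                      capacity = 4, A = 0.5, k = 1, tau = 0.35, eta = 3)
  tr <- simulate_behavior(cfg, subject_params = sp, seed = 8)
  ep <- simulate_eeg(tr, cfg, seed = 9)
  sl <- cpp_slope(ep$response)
  rec <- tr$cpp_slope[attr(sl, "trial_index")]
  keep <- tr$rt[attr(sl, "trial_index")] > 0.3
  expect_equal(cor(sl[keep], rec[keep], method = "spearman"), 1)
  # with unit slope-drift correlation the extracted slope orders with drift
  lead <- tr$drift_lead[attr(sl, "trial_index")]
  expect_gt(cor(sl[keep], lead[keep], method = "spearman"), 0.99)
})

test_that("noiseless injected value effect is recovered exactly by the GLM", {
  cfg <- generator_config(
    n_subjects = 1, design = design_spec(3, c(3, 3, 4)),
    eeg = list(n_channels = 16, sampling_rate = 40, noise_sd = 0,
               cpp_gain = 0, q_effect = 2, delay_effect = 0,
               setsize_effect = 0))
  tr <- simulate_behavior(cfg, seed = 10)
  ep <- simulate_eeg(tr, cfg, seed = 11)
  reg <- build_regressors(tr, "stimulus")
  bm <- single_trial_glm(ep$stimulus, reg)
  fcz <- match("FCz", bm$channels)
  t300 <- which.min(abs(bm$times - 300))
  expect_equal(bm$times[t300], 300)
  expect_equal(unname(bm$beta["q_rl", fcz, t300]), -2, tolerance = 1e-6)
})

test_that("null EEG produces no effects beyond the Bonferroni threshold almost everywhere", {
  cfg <- generator_config(
    n_subjects = 6, design = design_spec(2, c(3, 4)),
    eeg = list(n_channels = 8, sampling_rate = 32, cpp_gain = 0,
               q_effect = 0, delay_effect = 0, setsize_effect = 0,
               noise_sd = 5))
  tr <- simulate_behavior(cfg, seed = 12)
  below <- 0; total <- 0
  for (rep in 1:20) {
    ep <- simulate_eeg(tr, cfg, seed = 100 + rep)
    reg <- build_regressors(tr, "stimulus")
    bms <- lapply(unique(tr$subject), function(s) {
      sel <- attr(reg, "subject") == s
      r2 <- reg[sel, , drop = FALSE]
      attr(r2, "trial_rows") <- attr(reg, "trial_rows")[sel]
      single_trial_glm(ep$stimulus, r2)
    })
    gi <- group_inference(bms)
    below <- below + sum(!gi$mask)
    total <- total + length(gi$mask)
  }
  expect_gte(below / total, 0.99)
})

test_that("epoch sets have coherent geometry", {
  cfg <- generator_config(n_subjects = 1, design = design_spec(2, c(2, 3)),
                          eeg = list(n_channels = 12, sampling_rate = 64))
  tr <- simulate_behavior(cfg, seed = 13)
  ep <- simulate_eeg(tr, cfg, seed = 14)
  for (e in ep) {
    expect_s3_class(e, "epoch_set")
    expect_equal(dim(e$data)[1], sum(tr$included_in_eeg))
    expect_equal(dim(e$data)[2], 12)
    expect_equal(diff(e$times)[1], 1000 / 64, tolerance = 1e-9)
  }
  expect_identical(ep$stimulus$lock, "stimulus")
  expect_identical(ep$response$lock, "response")
  expect_error(simulate_eeg(tr[!tr$included_in_eeg, ], cfg), "no EEG")
})

test_that("the channel layout keeps the analysis electrodes at reduced montages", {
  lay64 <- eeg_layout(64)
  expect_equal(nrow(lay64), 64)
  expect_false(any(duplicated(lay64$channel)))
  lay8 <- eeg_layout(8)
  expect_true(all(c("CPz", "FCz", "Pz", "Cz") %in% lay8$channel))
})
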