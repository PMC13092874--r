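test_that("compiled replay likelihood matches the R module composition", {
  tr <- small_trials()
  cfg <- small_config()
  for (shift in c(0, 0.25)) {
    theta <- constrain_params(cfg$group_mean + shift)
    for (s in unique(tr$subject)) {
      tj <- tr[tr$subject == s, ]
      expect_equal(subject_loglik(tj, theta),
                   replay_loglik_oracle(tj, theta), tolerance = 1e-10)
    }
  }
})

test_that("the neural model with beta_slope = 0 reduces to the baseline exactly", {
  tr <- small_trials()
  tj <- tr[tr$subject == "s001", ]
  theta <- constrain_params(c(small_config()$group_mean, 0))
  z <- rnorm(nrow(tj))
  expect_identical(subject_loglik(tj, theta, slopes = z),
                   subject_loglik(tj, theta))
  # and a nonzero coefficient makes the likelihood slope-sensitive
  theta2 <- theta; theta2[["beta_slope"]] <- 0.2
  ll1 <- subject_loglik(tj, theta2, slopes = z)
  ll2 <- subject_loglik(tj, theta2, slopes = 2 * z)
  expect_false(isTRUE(all.equal(sum(ll1), sum(ll2))))
  expect_error(subject_loglik(tj, theta, slopes = z[-1]), "misaligned")
})

test_that("generating parameters beat globally perturbed ones in likelihood", {
  cfg <- generator_config(n_subjects = 10, design = design_spec(4, c(2, 3, 4, 5)))
  sp <- sample_subject_params(cfg, seed = 21)
  tr <- simulate_behavior(cfg, subject_params = sp, seed = 21)
  better <- 0
  for (j in 1:10) {
    tj <- tr[tr$subject == sprintf("s%03d", j), ]
    x <- sp$unconstrained[j, ]
    ll_true <- sum(subject_loglik(tj, constrain_params(x)))
    ll_pert <- sum(subject_loglik(tj, constrain_params(x + 1)))
    better <- better + (ll_true > ll_pert)
  }
  expect_equal(better, 10)
})

test_that("a zero-trial subject returns the prior location", {
  pri <- rlwm_priors()
  f <- rlwmlba:::fit_subject(small_trials()[0, ], NULL, pri, neural = FALSE,
                             n_starts = 2, n_draws = 50, seed = 1)
  expect_equal(unname(f$map_unconstrained[1:9]), unname(pri$mean),
               tolerance = 1e-4)
  expect_equal(unname(colMeans(f$draws)[1:9]), unname(pri$mean),
               tolerance = 3 * pri$map_sd / sqrt(50))
})

test_that("log-posterior is finite at the prior means for simulated data", {
  tr <- small_trials()
  theta <- constrain_params(rlwm_priors()$mean)
  for (s in unique(tr$subject))
    expect_true(is.finite(sum(subject_loglik(tr[tr$subject == s, ], theta))))
})

test_that("fitting is deterministic under a fixed seed", {
  tr <- small_trials()
  f1 <- rlwm_lba(tr, seed = 9, n_starts = 2, n_draws = 10)
  f2 <- rlwm_lba(tr, seed = 9, n_starts = 2, n_draws = 10)
  expect_identical(f1$group, f2$group)
  expect_identical(f1$pointwise_loglik, f2$pointwise_loglik)
  expect_s3_class(f1, "rlwm_lba_fit")
  expect_equal(length(coef(f1)), 9)
  expect_true(is.finite(logLik(f1)))
})

test_that("identical fits compare to a zero ELPD difference", {
  tr <- small_trials()
  f1 <- rlwm_lba(tr, seed = 9, n_starts = 2, n_draws = 10)
  cmp <- compare_elpd(f1, f1)
  expect_equal(cmp$elpd_diff, 0)
  expect_equal(cmp$se_diff, 0)
  f_sub <- rlwm_lba(tr[tr$subject == "s001", ], seed = 1, n_starts = 1,
                    n_draws = 10)
  expect_error(compare_elpd(f1, f_sub), "identical trial sets")
})

test_that("PSIS-LOO agrees with exact leave-one-out refitting on small data", {
  cfg <- generator_config(n_subjects = 3, design = design_spec(2, c(3, 3)))
  tr <- simulate_behavior(cfg, seed = 31)
  pri <- rlwm_priors()
  n_draws <- 400
  elpd_psis <- 0
  elpd_exact <- 0
  for (s in unique(tr$subject)) {
    tj <- tr[tr$subject == s, ]
    f <- rlwmlba:::fit_subject(tj, NULL, pri, neural = FALSE, n_starts = 2,
                               n_draws = 50, seed = 5)
    negpost_full <- function(x) {
      th <- constrain_params(c(x, 0))
      -(sum(subject_loglik(tj, th)) +
          sum(dnorm(x, pri$mean, pri$map_sd, log = TRUE)))
    }
    set.seed(500)
    mc_full <- rlwmlba:::rw_metropolis(negpost_full, f$map_unconstrained[1:9],
                                       f$vcov, n_keep = n_draws,
                                       burn = 1000L, thin = 12L)
    ll <- t(apply(mc_full$draws, 1L, function(x)
      subject_loglik(tj, constrain_params(c(x, 0)))))
    elpd_psis <- elpd_psis + sum(rlwmlba:::psis_loo_pointwise(ll)$elpd)
    for (i in seq_len(nrow(tj))) {
      # brute-force refit dropping trial i's likelihood term (the replayed
      # history is untouched, matching the pointwise LOO target)
      negpost_i <- function(x) {
        th <- constrain_params(c(x, 0))
        -(sum(subject_loglik(tj, th)[-i]) +
            sum(dnorm(x, pri$mean, pri$map_sd, log = TRUE)))
      }
      opt <- nlminb(f$map_unconstrained[1:9], negpost_i,
                    control = list(rel.tol = 1e-8, iter.max = 200))
      H <- optimHess(opt$par, negpost_i)
      cov_i <- rlwmlba:::laplace_cov(H, 9)
      set.seed(1000 + i)
      mc <- rlwmlba:::rw_metropolis(negpost_i, opt$par, cov_i,
                                    n_keep = 120, burn = 400L, thin = 6L)
      ll_i <- apply(mc$draws, 1L, function(x)
        subject_loglik(tj, constrain_params(c(x, 0)))[i])
      elpd_exact <- elpd_exact + (rlwmlba:::log_sum_exp(ll_i) - log(120))
    }
  }
  expect_lt(abs(elpd_psis - elpd_exact) / abs(elpd_exact), 0.05)
})

test_that("group-mean estimates are roughly calibrated across replicated cohorts", {
  # reduced-scale calibration: draw a group location near the generator
  # defaults, simulate a tiny cohort, refit, and check that the rank of the
  # truth within the group posterior is not grossly non-uniform
  base <- generator_config()$group_mean
  u <- c()
  for (r in 1:8) {
    set.seed(200 + r)
    gm <- base
    gm[c("tau", "eta")] <- gm[c("tau", "eta")] + rnorm(2, 0, 0.15)
    cfg <- generator_config(n_subjects = 3, group_mean = gm,
                            design = design_spec(3, c(2, 3, 4)))
    tr <- simulate_behavior(cfg, seed = 300 + r)
    fit <- rlwm_lba(tr, seed = 300 + r, n_starts = 2, n_draws = 30)
    g <- fit$group
    for (p in c("tau", "eta")) {
      truth <- constrain_params(stats::setNames(gm, names(base)))[[p]]
      row <- g[g$parameter == p, ]
      u <- c(u, pnorm((truth - row$mean) / max(row$se, 1e-6)))
    }
  }
  counts <- table(cut(u, breaks = c(0, 0.25, 0.5, 0.75, 1)))
  p <- suppressWarnings(chisq.test(counts)$p.value)  # small-count approx
  expect_gt(p, 0.01)
})
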