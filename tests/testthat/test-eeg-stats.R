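make_epochs <- function(data, fs = 64, lock = "stimulus",
                        channels = eeg_layout(dim(data)[2])$channel) {
  n_samp <- dim(data)[3]
  times <- (seq_len(n_samp) - ceiling(n_samp / 2)) * 1000 / fs
  epoch_set(data, times, channels, fs, lock)
}

test_that("regressors are z-scored within subject with n-1 normalization", {
  tr <- small_trials()
  reg <- build_regressors(tr, "stimulus")
  subj <- attr(reg, "subject")
  for (nm in names(reg)) {
    for (s in unique(subj)) {
      v <- reg[[nm]][subj == s]
      expect_equal(mean(v), 0, tolerance = 1e-8)
      expect_equal(sd(v), 1, tolerance = 1e-8)
    }
  }
  expect_equal(names(reg), c("set_size", "delay", "q_rl"))
  expect_equal(names(build_regressors(tr, "response")), "drift")
  # hand-computed z-scores for a toy delay column
  z <- (c(1, 2, 3, 4) - 2.5) / sd(c(1, 2, 3, 4))
  expect_equal(round(z, 4), c(-1.1619, -0.3873, 0.3873, 1.1619))
})

test_that("degenerate predictors are flagged and dropped to zero", {
  tr <- small_trials()
  tr$set_size <- 3L   # constant within (and across) subjects
  expect_warning(reg <- build_regressors(tr, "stimulus"), "zero variance")
  expect_true(all(reg$set_size == 0))
})

test_that("the mass-univariate GLM is exact ordinary least squares", {
  set.seed(21)
  n <- 40
  z <- as.data.frame(scale(matrix(rnorm(n * 3), n)))
  names(z) <- c("a", "b", "c")
  dat <- array(rnorm(n * 4 * 6, sd = 0.5), c(n, 4, 6))
  dat[, 2, 3] <- 2 * z$a            # noiseless injected effect
  dat[, 3, 4] <- dat[, 3, 4] + 1.5  # intercept shift
  ep <- make_epochs(dat)
  bm <- single_trial_glm(ep, z[, 1:2])
  bm_aug <- single_trial_glm(ep, z)      # add an inert third predictor
  # pseudoinverse oracle
  X <- cbind(1, as.matrix(z[, 1:2]))
  B <- solve(t(X) %*% X, t(X) %*% matrix(dat, n))
  expect_equal(as.numeric(bm$beta), as.numeric(B), tolerance = 1e-8)
  expect_equal(unname(bm$beta["a", 2, 3]), 2, tolerance = 1e-10)
  expect_equal(unname(bm$beta[, 2, 3]), unname(bm_aug$beta[1:3, 2, 3]),
               tolerance = 1e-10)
  dup <- cbind(z, a2 = z$a)
  expect_error(single_trial_glm(ep, dup), "rank-deficient")
})

test_that("Yuen's trimmed t matches the textbook formula", {
  x <- c(-0.8, -0.3, 0.1, 0.4, 0.5, 0.9, 1.2, 1.8, 2.6, 7.5)
  res <- rlwmlba:::yuen_t(x)
  # independent computation: 20% trim, winsorized variance, df = h - 1
  n <- 10; g <- 2; h <- n - 2 * g
  xs <- sort(x)
  tm <- mean(xs[3:8])
  xw <- pmin(pmax(xs, xs[3]), xs[8])
  se <- sqrt(var(xw)) / (0.6 * sqrt(n))
  expect_equal(unname(res["tmean"]), tm, tolerance = 1e-10)
  expect_equal(unname(res["t"]), tm / se, tolerance = 1e-10)
  expect_equal(unname(res["p"]), 2 * pt(-abs(tm / se), h - 1),
               tolerance = 1e-10)
  expect_equal(unname(res["df"]), h - 1)
})

test_that("group inference masks nothing under null betas and everything degenerate-constant", {
  d <- c(2, 3, 5)
  set.seed(31)
  null_betas <- lapply(1:8, function(i)
    structure(list(beta = array(rnorm(prod(d)), d,
                                dimnames = list(c("(Intercept)", "x"), NULL, NULL)),
                   predictors = c("(Intercept)", "x"),
                   channels = paste0("ch", 1:3), times = 1:5),
              class = "beta_maps"))
  gi <- group_inference(null_betas, alpha = 0.05)
  expect_equal(gi$threshold, 0.05 / (2 * 3 * 5))
  zero <- null_betas
  for (i in seq_along(zero)) zero[[i]]$beta[] <- 0
  expect_equal(sum(group_inference(zero)$mask), 0)
  const <- null_betas
  for (i in seq_along(const)) const[[i]]$beta[] <- 1.3
  gi_c <- group_inference(const)
  expect_true(all(gi_c$mask))
  expect_error(group_inference(null_betas[1:3]), "at least 5")
})

test_that("corrected ERPs recombine intercept and scaled beta maps", {
  d <- c(2, 3, 5)
  bm <- structure(list(beta = array(seq_len(prod(d)), d,
                                    dimnames = list(c("(Intercept)", "q"), NULL, NULL)),
                       predictors = c("(Intercept)", "q"),
                       channels = paste0("ch", 1:3), times = 1:5),
                  class = "beta_maps")
  w <- corrected_erp(bm, "q", levels = c(1, 3), z_mean = 2, z_sd = 1)
  expect_equal(w[["1"]], bm$beta[1, , ] - bm$beta[2, , ])
  expect_equal(w[["3"]], bm$beta[1, , ] + bm$beta[2, , ])
  # symmetric levels straddle the intercept map symmetrically
  expect_equal((w[["1"]] + w[["3"]]) / 2, bm$beta[1, , ])
  bm0 <- bm; bm0$beta[2, , ] <- 0
  w0 <- corrected_erp(bm0, "q", levels = c(0, 4), z_mean = 2, z_sd = 1)
  expect_equal(w0[["0"]], w0[["4"]])
  expect_error(corrected_erp(bm, "nope", 1, 0, 1), "not in model")
  expect_warning(corrected_erp(bm, "q", levels = 50, z_mean = 2, z_sd = 1),
                 "outside")
})

test_that("CPP slope reads the landmark samples", {
  dat <- array(0, c(2, 4, 91))
  fs <- 64
  times <- (seq_len(91) - 46) * 1000 / fs
  i1 <- which.min(abs(times - (-200))); i2 <- which.min(abs(times - (-50)))
  dat[1, 2, i1] <- 2; dat[1, 2, i2] <- 5
  ep <- epoch_set(dat, times, c("Cz", "CPz", "Pz", "POz"), fs, "response")
  sl <- cpp_slope(ep)
  expect_equal(sl[1], (5 - 2) / 150)
  expect_equal(sl[2], 0)
  # a pure linear ramp is recovered up to sample discretization
  m <- 0.04  # uV/ms
  ramp <- array(0, c(1, 4, 91)); ramp[1, 2, ] <- m * times
  ep2 <- epoch_set(ramp, times, c("Cz", "CPz", "Pz", "POz"), fs, "response")
  expect_equal(cpp_slope(ep2)[1], m * (times[i2] - times[i1]) / 150,
               tolerance = 1e-12)
  expect_lt(abs(cpp_slope(ep2)[1] - m), m * (1000 / fs) / 150 + 1e-12)
  expect_error(cpp_slope(ep, channel = "XX"), "not present")
  expect_error(cpp_slope(make_epochs(dat, lock = "stimulus",
                                     channels = c("Cz", "CPz", "Pz", "POz"))),
               "response-locked")
})

test_that("quartiles are rank-based with tied values sharing a quartile", {
  expect_equal(quartile_assign(1:8, rep("g", 8)), c(1, 1, 2, 2, 3, 3, 4, 4))
  # tied values land in the same quartile instead of being scrambled
  expect_equal(quartile_assign(c(1, 1, 1, 1, 2, 2, 2, 2), rep("g", 8)),
               c(2, 2, 2, 2, 4, 4, 4, 4))
  expect_warning(q_tie <- quartile_assign(rep(1, 8), rep("g", 8)),
                 "degenerate")
  expect_equal(length(unique(q_tie)), 1L)
  expect_warning(quartile_assign(1:3, rep("g", 3)), "fewer than 4")
  set.seed(41)
  v <- rnorm(103)
  q <- quartile_assign(v, rep("g", 103))
  expect_true(all(abs(table(q) - 103 / 4) <= 1))
  # grouping is respected
  q2 <- quartile_assign(c(1:8, 1:8), rep(c("a", "b"), each = 8))
  expect_equal(q2[1:8], q2[9:16])
})

test_that("slope regression recovers exact constructed coefficients", {
  d <- expand.grid(q_rl_quartile = 1:4, q_wm_quartile = 1:4,
                   set_size = c(2, 3, 4, 5), subject = c("a", "b"))
  d$cpp_slope <- 0.1 * d$q_rl_quartile + ifelse(d$subject == "a", 0.3, -0.2)
  suppressWarnings(sr <- slope_regression(d))  # zero-residual fit
  co <- sr$coefficients
  expect_equal(co$estimate[co$predictor == "q_rl"], rep(0.1, 4),
               tolerance = 1e-10)
  expect_equal(co$estimate[co$predictor == "q_wm"], rep(0, 4),
               tolerance = 1e-10)
})

test_that("slope regression matches a least-squares oracle on a toy table", {
  set.seed(51)
  d <- data.frame(q_rl_quartile = sample(1:4, 40, TRUE),
                  q_wm_quartile = sample(1:4, 40, TRUE),
                  set_size = sample(c(2, 5), 40, TRUE),
                  subject = rep(c("a", "b"), 20))
  d$cpp_slope <- rnorm(40)
  sr <- slope_regression(d)
  X <- model.matrix(~ subject + (q_rl_quartile + q_wm_quartile) * factor(set_size), d)
  beta <- solve(t(X) %*% X, t(X) %*% d$cpp_slope)
  est_rl_5 <- unname(beta["q_rl_quartile", 1] +
                       beta["q_rl_quartile:factor(set_size)5", 1])
  co <- sr$coefficients
  expect_equal(co$estimate[co$predictor == "q_rl" & co$set_size == 5],
               est_rl_5, tolerance = 1e-8)
  expect_equal(co$estimate[co$predictor == "q_rl" & co$set_size == 2],
               unname(beta["q_rl_quartile", 1]), tolerance = 1e-8)
})
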