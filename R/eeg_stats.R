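#' Build z-scored trial regressors for the single-trial ERP GLMs
#'
#' Stimulus-locked models carry three predictors — z(set size), z(delay),
#' z(Q_RL of the chosen option) — plus an intercept; response-locked models
#' carry z(drift rate of the chosen option) plus an intercept. Predictors are
#' z-transformed within subject (sd with denominator n-1). Only EEG-included
#' trials enter; for the stimulus lock, trials with undefined delay are
#' dropped. A predictor with zero variance within a subject is flagged and
#' dropped for that subject with a warning.
#'
#' @param trials Trial table with latent columns and `included_in_eeg`.
#' @param lock `"stimulus"` or `"response"`.
#' @return data.frame of z-scored predictors with attributes `trial_rows`
#'   (row indices into `trials`), `subject`, `dropped` (per-subject dropped
#'   predictors) and `scaling` (per-subject means/sds used).
#' @export
build_regressors <- function(trials, lock = c("stimulus", "response")) {
  lock <- match.arg(lock)
  keep <- which(trials$included_in_eeg)
  if (lock == "stimulus") keep <- keep[!is.na(trials$delay[keep])]
  raw <- if (lock == "stimulus")
    data.frame(set_size = as.numeric(trials$set_size[keep]),
               delay = as.numeric(trials$delay[keep]),
               q_rl = trials$q_rl_chosen[keep])
  else
    data.frame(drift = trials$drift_chosen[keep])
  subj <- trials$subject[keep]
  dropped <- list()
  scaling <- list()
  for (nm in names(raw)) {
    mu <- tapply(raw[[nm]], subj, mean)
    sdv <- tapply(raw[[nm]], subj, stats::sd)
    bad <- names(sdv)[!is.finite(sdv) | sdv == 0]
    if (length(bad)) {
      warning(sprintf("predictor '%s' has zero variance for subject(s) %s; dropped there",
                      nm, paste(bad, collapse = ", ")))
      for (b in bad) dropped[[b]] <- c(dropped[[b]], nm)
      sdv[bad] <- Inf   # z becomes 0 for those subjects
    }
    scaling[[nm]] <- data.frame(subject = names(mu), mean = as.numeric(mu),
                                sd = as.numeric(sdv))
    raw[[nm]] <- (raw[[nm]] - mu[as.character(subj)]) / sdv[as.character(subj)]
  }
  structure(raw, trial_rows = keep, subject = subj, lock = lock,
            dropped = dropped, scaling = scaling)
}

#' Single-trial mass-univariate GLM
#'
#' Ordinary least squares of the epoched EEG voltage at every channel and
#' sample on the trial regressors (plus an intercept modelling the average
#' ERP), for one subject.
#'
#' @param epochs An [epoch_set()].
#' @param regressors data.frame of z-scored predictors from
#'   [build_regressors()], or any numeric data.frame aligned with the epochs'
#'   trials. If it carries a `trial_rows` attribute, epochs are matched to it
#'   via the epoch set's `trial_index`.
#' @return Object of class `beta_maps`: array `predictors x channels x
#'   samples` (first predictor `(Intercept)`), plus `channels` and `times`.
#' @export
single_trial_glm <- function(epochs, regressors) {
  rows <- attr(regressors, "trial_rows")
  if (!is.null(rows)) {
    m <- match(rows, epochs$trial_index)
    if (anyNA(m)) stop("epochs do not cover the regressor trials")
    dat <- epochs$data[m, , , drop = FALSE]
  } else {
    if (nrow(regressors) != dim(epochs$data)[1])
      stop("regressors misaligned with epochs")
    dat <- epochs$data
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(as.data.frame(regressors)))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient design")
  n_tr <- dim(dat)[1]
  Y <- matrix(dat, nrow = n_tr)   # trials x (channels*samples)
  B <- qr.coef(qx, Y)
  beta <- array(B, c(ncol(X), dim(dat)[2], dim(dat)[3]),
                dimnames = list(colnames(X), epochs$channels, NULL))
  structure(list(beta = beta, predictors = colnames(X),
                 channels = epochs$channels, times = epochs$times,
                 lock = epochs$lock),
            class = "beta_maps")
}

# One-sample trimmed-mean t (Tukey-McLaughlin/Yuen): 20% trim per tail,
# winsorized variance, df = h - 1 with h = n - 2*floor(trim*n).
yuen_t <- function(x, trim = 0.2, mu = 0) {
  n <- length(x)
  g <- floor(trim * n)
  h <- n - 2L * g
  if (h < 2L) stop("insufficient observations after trimming")
  xs <- sort(x)
  tm <- mean(xs[(g + 1L):(n - g)])
  xw <- pmin(pmax(xs, xs[g + 1L]), xs[n - g])
  sw2 <- stats::var(xw)
  se <- sqrt(sw2) / ((1 - 2 * trim) * sqrt(n))
  if (se == 0) {
    t <- if (tm == mu) 0 else sign(tm - mu) * Inf
    p <- if (tm == mu) 1 else 0
  } else {
    t <- (tm - mu) / se
    p <- 2 * stats::pt(-abs(t), df = h - 1L)
  }
  c(tmean = tm, t = t, p = p, df = h - 1L)
}

#' Group-level robust inference over beta maps
#'
#' For every predictor, channel and sample, computes the 20% trimmed mean of
#' the subject beta weights and tests it against zero with a one-sample
#' trimmed-mean (Yuen) t-test using the winsorized variance
#' (df = h - 1, h the number of observations surviving the trim). P-values
#' are Bonferroni-corrected across electrodes, time points and estimated
#' parameters: the significance mask is `p < alpha / (E * T * P)`.
#'
#' @param beta_list List of [single_trial_glm()] results, one per subject
#'   (same predictors, channels, times).
#' @param alpha Family-wise error level before correction.
#' @param trim Trim proportion per tail.
#' @return Object of class `group_stat_map` with arrays `tmean`, `t`, `p`,
#'   `mask` (`predictors x channels x samples`) and correction metadata.
#' @export
group_inference <- function(beta_list, alpha = 0.05, trim = 0.2) {
  if (length(beta_list) < 5L) stop("at least 5 subjects required")
  d <- dim(beta_list[[1]]$beta)
  preds <- beta_list[[1]]$predictors
  stack <- vapply(beta_list, function(b) b$beta, beta_list[[1]]$beta)
  n_pts <- prod(d)
  flat <- matrix(stack, n_pts, length(beta_list))
  res <- apply(flat, 1L, yuen_t, trim = trim)
  shape <- function(v) array(v, d, dimnames = dimnames(beta_list[[1]]$beta))
  E <- d[2]; Tm <- d[3]; P <- d[1]
  thresh <- alpha / (E * Tm * P)
  p <- shape(res["p", ])
  structure(list(tmean = shape(res["tmean", ]), t = shape(res["t", ]),
                 p = p, mask = p < thresh,
                 alpha = alpha, n_electrodes = E, n_timepoints = Tm,
                 n_predictors = P, n_comparisons = E * Tm * P,
                 threshold = thresh, trim = trim,
                 channels = beta_list[[1]]$channels,
                 times = beta_list[[1]]$times),
            class = "group_stat_map")
}

#' @export
print.group_stat_map <- function(x, ...) {
  cat(sprintf("group_stat_map: %d predictors x %d channels x %d samples\n",
              x$n_predictors, x$n_electrodes, x$n_timepoints))
  cat(sprintf("  Bonferroni: alpha %.3g / (%d comparisons) = %.3g; %d significant points\n",
              x$alpha, x$n_comparisons, x$threshold, sum(x$mask)))
  invisible(x)
}

#' Reconstruct corrected ERPs from beta maps
#'
#' The ERP attributable to one predictor at a given raw level is the
#' intercept map plus the predictor's beta map times the z-score of that
#' level; all other predictors are held at their mean (z = 0), removing their
#' modelled effects.
#'
#' @param betas A [single_trial_glm()] result, or a [group_inference()]
#'   result (its trimmed-mean maps are used).
#' @param predictor Predictor name.
#' @param levels Raw predictor values to reconstruct.
#' @param z_mean,z_sd Standardization used when the predictor entered the
#'   model (e.g. from the `scaling` attribute of [build_regressors()]).
#' @return Named list of `channels x samples` waveform matrices, one per
#'   level.
#' @export
corrected_erp <- function(betas, predictor, levels, z_mean, z_sd) {
  maps <- if (inherits(betas, "group_stat_map")) betas$tmean else betas$beta
  preds <- dimnames(maps)[[1]]
  if (!predictor %in% preds) stop("predictor not in model")
  z <- (levels - z_mean) / z_sd
  if (any(abs(z) > 3))
    warning("some levels lie outside the standardization support")
  out <- lapply(z, function(zz)
    maps["(Intercept)", , ] + zz * maps[predictor, , ])
  names(out) <- as.character(levels)
  out
}

#' Extract the per-trial CPP slope
#'
#' Reads the amplitude at the samples nearest -200 ms and -50 ms before the
#' response at one centro-parietal channel and returns the slope
#' `(amp(-50) - amp(-200)) / 150` in microvolts/ms for every trial.
#'
#' @param epochs Response-locked [epoch_set()].
#' @param channel Channel label (default `"CPz"`).
#' @return Numeric vector of slopes, one per trial, with the epoch trial
#'   index attached as attribute `"trial_index"`.
#' @export
cpp_slope <- function(epochs, channel = "CPz") {
  if (epochs$lock != "response") stop("response-locked epochs required")
  ch <- match(channel, epochs$channels)
  if (is.na(ch)) stop(sprintf("channel %s not present", channel))
  if (min(epochs$times) > -200 || max(epochs$times) < -50)
    stop("epoch window does not cover -200..-50 ms")
  i1 <- which.min(abs(epochs$times - (-200)))
  i2 <- which.min(abs(epochs$times - (-50)))
  s <- (epochs$data[, ch, i2] - epochs$data[, ch, i1]) / 150
  attr(s, "trial_index") <- epochs$trial_index
  s
}

#' Assign within-group quartiles
#'
#' Rank-based quartiles (labels 1-4) assigned within each grouping cell
#' (typically subject x set size). Tied values share a quartile (midrank
#' ties): under deterministic feedback the Q-value trajectories produce
#' heavily tied values, and breaking ties arbitrarily would scramble equal
#' values across quartiles and destroy the very association the quartile
#' analysis measures. Cells with fewer than 4 trials, or with all values
#' identical, are flagged with a warning.
#'
#' @param values Numeric vector.
#' @param group Grouping factor (or interaction) of the same length.
#' @return Integer vector of quartile labels in 1-4.
#' @export
quartile_assign <- function(values, group) {
  group <- as.factor(group)
  if (any(tabulate(group) == 0L)) group <- droplevels(group)
  small <- names(which(table(group) < 4L))
  if (length(small))
    warning(sprintf("group(s) with fewer than 4 trials: %s",
                    paste(small, collapse = ", ")))
  out <- integer(length(values))
  degenerate <- character(0)
  for (g in levels(group)) {
    sel <- group == g
    if (length(unique(values[sel])) == 1L) degenerate <- c(degenerate, g)
    r <- rank(values[sel], ties.method = "average")
    out[sel] <- pmax(1L, pmin(4L, as.integer(ceiling(4 * r / sum(sel)))))
  }
  if (length(degenerate))
    warning(sprintf("degenerate group(s) with all-equal values: %s",
                    paste(degenerate, collapse = ", ")))
  out
}

#' Regress CPP slope on RL and WM value quartiles across set sizes
#'
#' Linear model `cpp_slope ~ subject + (q_rl_quartile + q_wm_quartile) *
#' set_size` with quartiles numeric (1-4), set size categorical and fixed
#' per-subject intercepts. Reports, for each set size, the simple slope of
#' the Q-RL and Q-WM quartiles with cluster-robust (by subject) 95%
#' confidence intervals.
#'
#' @param slopes data.frame with columns `cpp_slope`, `q_rl_quartile`,
#'   `q_wm_quartile`, `set_size`, `subject`.
#' @return Object of class `slope_regression`: data.frame `coefficients`
#'   (`set_size, predictor, estimate, se, ci_lo, ci_hi`) plus the fitted
#'   `lm` in `$model`.
#' @export
slope_regression <- function(slopes) {
  req <- c("cpp_slope", "q_rl_quartile", "q_wm_quartile", "set_size", "subject")
  if (!all(req %in% names(slopes))) stop("missing required columns")
  d <- slopes
  d$set_size <- factor(d$set_size)
  d$subject <- factor(d$subject)
  form <- cpp_slope ~ subject + (q_rl_quartile + q_wm_quartile) * set_size
  if (nlevels(d$subject) == 1L)
    form <- cpp_slope ~ (q_rl_quartile + q_wm_quartile) * set_size
  fit <- stats::lm(form, data = d)
  if (anyNA(stats::coef(fit))) stop("rank-deficient design")
  V <- sandwich::vcovCL(fit, cluster = d$subject)
  cf <- stats::coef(fit)
  ss_levels <- levels(d$set_size)
  rows <- list()
  for (pred in c("q_rl_quartile", "q_wm_quartile")) {
    for (s in ss_levels) {
      contr <- stats::setNames(numeric(length(cf)), names(cf))
      contr[pred] <- 1
      inter <- paste0(pred, ":set_size", s)
      if (inter %in% names(cf)) contr[inter] <- 1
      est <- sum(contr * cf)
      se <- sqrt(drop(t(contr) %*% V %*% contr))
      rows[[length(rows) + 1L]] <- data.frame(
        set_size = as.integer(s), predictor = sub("_quartile", "", pred),
        estimate = est, se = se,
        ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se)
    }
  }
  structure(list(coefficients = do.call(rbind, rows), model = fit),
            class = "slope_regression")
}

#' @export
print.slope_regression <- function(x, ...) {
  cat("CPP-slope ~ value-quartile regression (cluster-robust 95% CI)\n")
  print(x$coefficients, row.names = FALSE, digits = 3)
  invisible(x)
}
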