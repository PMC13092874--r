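#' Idealized 64-channel scalp layout
#'
#' A 10/20-style montage of 64 labelled electrodes with 2-D scalp-plane
#' coordinates (x: left negative to right positive; y: posterior negative to
#' anterior positive), used for Gaussian spatial weighting of simulated
#' components and for neighborhood queries. When fewer channels are
#' requested, electrodes are kept in order of a priority list that retains
#' the midline and centro-parietal sites (CPz, FCz, Pz, Cz, ...) the analyses
#' rely on.
#'
#' @param n_channels Number of electrodes to return (<= 64).
#' @return data.frame with columns `channel`, `x`, `y`.
#' @export
eeg_layout <- function(n_channels = 64L) {
  labs <- c("Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3",
            "FC1", "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1",
            "P3", "P5", "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz",
            "Pz", "CPz", "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4",
            "F6", "F8", "FT8", "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4",
            "C6", "T8", "TP8", "CP6", "CP4", "CP2", "P2", "P4", "P6", "P8",
            "P10", "PO8", "PO4", "O2")
  rowy <- c(Fp = 0.9, AF = 0.7, F = 0.5, FT = 0.3, FC = 0.3, T = 0, C = 0,
            TP = -0.3, CP = -0.3, P = -0.5, PO = -0.7, O = -0.9, I = -1.05)
  parse_one <- function(l) {
    m <- regmatches(l, regexec("^([A-Za-z]+?)(z|[0-9]+)$", l))[[1]]
    row <- m[2]; col <- m[3]
    y <- rowy[[row]]
    if (col == "z") x <- 0
    else {
      d <- as.integer(col)
      mag <- c(`1` = 0.2, `2` = 0.2, `3` = 0.45, `4` = 0.45, `5` = 0.7,
               `6` = 0.7, `7` = 0.9, `8` = 0.9, `9` = 1.05, `10` = 1.05)[[col]]
      x <- if (d %% 2 == 1) -mag else mag
    }
    c(x, y)
  }
  xy <- t(vapply(labs, parse_one, numeric(2)))
  layout <- data.frame(channel = labs, x = xy[, 1], y = xy[, 2],
                       stringsAsFactors = FALSE)
  priority <- c("CPz", "FCz", "Pz", "Cz", "Fz", "POz", "AFz", "Oz", "Fpz",
                "Iz", "CP1", "CP2", "FC1", "FC2", "P1", "P2", "C1", "C2",
                "CP3", "CP4", "FC3", "FC4", "P3", "P4", "C3", "C4", "F1",
                "F2", "PO3", "PO4")
  ord <- c(match(priority, labs), setdiff(seq_along(labs), match(priority, labs)))
  out <- layout[ord[seq_len(min(n_channels, 64L))], ]
  rownames(out) <- NULL
  out
}

#' Construct an epoched EEG container
#'
#' @param data Numeric array `trials x channels x samples` (microvolts).
#' @param times Sample times in ms relative to the lock event.
#' @param channels Channel labels.
#' @param sampling_rate Sampling rate in Hz.
#' @param lock `"stimulus"` or `"response"`.
#' @param trial_index Integer keys into the originating trial table.
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, channels, sampling_rate, lock,
                      trial_index = seq_len(dim(data)[1])) {
  stopifnot(length(dim(data)) == 3L,
            dim(data)[2] == length(channels),
            dim(data)[3] == length(times),
            dim(data)[1] == length(trial_index))
  lock <- match.arg(lock, c("stimulus", "response"))
  dt <- diff(times)
  if (length(dt) && max(abs(dt - 1000 / sampling_rate)) > 1e-6)
    stop("times must be uniform at 1000/sampling_rate ms")
  structure(list(data = data, times = times, channels = as.character(channels),
                 sampling_rate = sampling_rate, lock = lock,
                 trial_index = as.integer(trial_index)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch_set: %d trials x %d channels x %d samples, %g Hz, %s-locked [%g, %g] ms\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$sampling_rate, x$lock, min(x$times), max(x$times)))
  invisible(x)
}

# AR(1) noise matrix (n_series x n_samples) with marginal sd `sd` and
# per-sample coefficient `ar`; stationary initialization.
ar1_noise <- function(n_series, n_samples, ar, sd) {
  if (sd == 0) return(matrix(0, n_series, n_samples))
  innov_sd <- sd * sqrt(1 - ar^2)
  e <- matrix(stats::rnorm(n_series * n_samples, 0, innov_sd), n_samples)
  e[1, ] <- stats::rnorm(n_series, 0, sd)
  x <- apply(e, 2L, function(col)
    stats::filter(col, ar, method = "recursive", init = 0))
  t(matrix(x, n_samples))
}

#' Generate epoched EEG for simulated trials
#'
#' For each EEG-included trial a continuous signal spanning the epoch windows
#' around stimulus and response is composed of: a centro-parietal ramp (CPP)
#' whose onset precedes the response by at most `cpp_max_buildup` seconds and
#' whose buildup rate is the trial's generated CPP slope (scaled by
#' `cpp_gain`), decaying back to baseline after the response; a
#' fronto-central Gaussian component at 300 ms post-stimulus with amplitude
#' `-(q_effect * z(Q_RL) + delay_effect * z(delay))`; a parietal Gaussian
#' component at 540 ms with amplitude `setsize_effect * z(set_size)`; and
#' AR(1) noise per channel. Components project to the scalp with Gaussian
#' spatial weights around their center electrodes. Stimulus-locked and
#' response-locked epochs are cut from the same continuous signal.
#'
#' @param trials Trial table from [simulate_behavior()] (latent columns and
#'   `included_in_eeg` present).
#' @param config A [generator_config()]; its `eeg` list supplies geometry,
#'   component amplitudes and the noise model.
#' @param seed Integer seed.
#' @return List with elements `stimulus` and `response`, each an
#'   [epoch_set()] over the included trials.
#' @export
simulate_eeg <- function(trials, config, seed = config$seed) {
  e <- config$eeg
  lay <- eeg_layout(e$n_channels)
  fs <- e$sampling_rate
  win <- e$window
  keep <- which(trials$included_in_eeg)
  if (length(keep) == 0L) stop("no EEG-included trials")
  need <- c("q_rl_chosen", "cpp_slope", "drift_chosen", "delay", "rt")
  if (!all(need %in% names(trials))) stop("missing latent columns")
  local_rng(seed, "eeg")

  wts <- function(center) {
    ctr <- lay[lay$channel == center, ]
    if (nrow(ctr) == 0L) stop(sprintf("channel %s not in layout", center))
    exp(-((lay$x - ctr$x)^2 + (lay$y - ctr$y)^2) / (2 * e$spatial_sigma^2))
  }
  w_q <- wts(e$q_center); w_del <- wts(e$delay_center)
  w_ss <- wts(e$setsize_center); w_cpp <- wts(e$cpp_center)

  # Within-subject z-scoring of the stimulus-locked effect drivers, using the
  # moments of the analysis set (included trials with a defined delay) so the
  # injected amplitudes match what the stimulus-locked GLM estimates exactly.
  sub <- trials$subject[keep]
  del <- trials$delay[keep]
  zcol <- function(v) {
    out <- numeric(length(v))
    for (s in unique(sub)) {
      sel <- sub == s
      base <- sel & !is.na(del)
      m <- mean(v[base]); sdv <- stats::sd(v[base])
      if (!is.finite(sdv) || sdv == 0) { m <- 0; sdv <- Inf }
      out[sel] <- (v[sel] - m) / sdv
    }
    out
  }
  z_q <- zcol(trials$q_rl_chosen[keep])
  z_del <- zcol(ifelse(is.na(del), 0, del))
  z_del[is.na(del)] <- 0   # undefined delay contributes no delay effect
  z_ss <- zcol(as.numeric(trials$set_size[keep]))

  k_win <- round(win * fs)
  times_ms <- (k_win[1]:k_win[2]) / fs * 1000
  n_samp <- length(times_ms)
  n_ch <- nrow(lay)
  stim_arr <- array(0, c(length(keep), n_ch, n_samp))
  resp_arr <- array(0, c(length(keep), n_ch, n_samp))

  for (ti in seq_along(keep)) {
    i <- keep[ti]
    rt <- trials$rt[i]
    r0 <- round(rt * fs)               # response sample on the stimulus grid
    kk <- k_win[1]:(r0 + k_win[2])     # continuous grid covering both epochs
    tt <- kk / fs
    base <- numeric(length(tt))
    sig <- matrix(0, n_ch, length(tt))

    # CPP ramp: linear rise to the response, then linear return to baseline
    rate <- e$cpp_gain * trials$cpp_slope[i] * 1000   # uV/ms -> uV/s
    t_on <- rt - min(rt, e$cpp_max_buildup)
    ramp <- base
    rising <- tt >= t_on & tt <= rt
    ramp[rising] <- (tt[rising] - t_on) * rate
    peak <- (rt - t_on) * rate
    falling <- tt > rt & tt <= rt + e$cpp_decay
    ramp[falling] <- peak * (1 - (tt[falling] - rt) / e$cpp_decay)
    sig <- sig + outer(w_cpp, ramp)

    # stimulus-locked Gaussian components
    amp_q <- -(e$q_effect * z_q[ti])
    amp_d <- -(e$delay_effect * z_del[ti])
    amp_s <- e$setsize_effect * z_ss[ti]
    g1 <- exp(-(tt - e$comp_latencies[["q"]])^2 / (2 * e$comp_widths[["q"]]^2))
    g2 <- exp(-(tt - e$comp_latencies[["setsize"]])^2 /
                (2 * e$comp_widths[["setsize"]]^2))
    sig <- sig + outer(w_q * amp_q + w_del * amp_d, g1) + outer(w_ss * amp_s, g2)

    sig <- sig + ar1_noise(n_ch, length(tt), e$noise_ar, e$noise_sd)

    # sample k on the stimulus grid sits at column k - k_win[1] + 1
    stim_arr[ti, , ] <- sig[, seq_len(n_samp)]
    resp_arr[ti, , ] <- sig[, (r0 + k_win[1]):(r0 + k_win[2]) - k_win[1] + 1L]
  }
  list(
    stimulus = epoch_set(stim_arr, times_ms, lay$channel, fs, "stimulus", keep),
    response = epoch_set(resp_arr, times_ms, lay$channel, fs, "response", keep)
  )
}
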