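#' Specify one block of the stimulus-response association task
#'
#' A block presents `set_size` stimuli, each mapped deterministically to one of
#' three actions. Each stimulus is presented repeatedly until the learner has
#' answered it correctly on at least `criterion_hits` of its last
#' `criterion_window` presentations (checked from `min_presentations` onward),
#' or until `max_presentations` is reached. The stimulus-to-action map need not
#' be injective: several stimuli may share the same correct action.
#'
#' @param block_index Integer block label.
#' @param set_size Number of stimuli in the block (2 to 5).
#' @param stimulus_ids Character or integer identifiers, one per stimulus.
#'   Defaults to `"s1" ... "s<set_size>"`.
#' @param correct_action Integer vector in `1:3`, the correct action for each
#'   stimulus (named by or aligned with `stimulus_ids`).
#' @param min_presentations,max_presentations Floor and ceiling on the number
#'   of presentations per stimulus (defaults 9 and 15).
#' @param criterion_hits,criterion_window The learning criterion: a stimulus is
#'   retired once at least `criterion_hits` of its last `criterion_window`
#'   presentations were answered correctly (defaults 4 of 5).
#' @return An object of class `block_spec`.
#' @export
block_spec <- function(block_index, set_size, stimulus_ids = NULL,
                       correct_action = NULL,
                       min_presentations = 9L, max_presentations = 15L,
                       criterion_hits = 4L, criterion_window = 5L) {
  set_size <- as.integer(set_size)
  if (set_size < 2L || set_size > 5L)
    stop("set_size must be between 2 and 5")
  if (is.null(stimulus_ids))
    stimulus_ids <- paste0("s", seq_len(set_size))
  if (length(stimulus_ids) != set_size)
    stop("stimulus_ids must have length set_size")
  if (is.null(correct_action))
    correct_action <- rep_len(1:3, set_size)
  correct_action <- as.integer(correct_action)
  if (length(correct_action) != set_size || any(!correct_action %in% 1:3))
    stop("correct_action must map every stimulus to an action in 1:3")
  structure(list(
    block_index = as.integer(block_index),
    set_size = set_size,
    stimulus_ids = as.character(stimulus_ids),
    correct_action = stats::setNames(correct_action, as.character(stimulus_ids)),
    min_presentations = as.integer(min_presentations),
    max_presentations = as.integer(max_presentations),
    criterion_hits = as.integer(criterion_hits),
    criterion_window = as.integer(criterion_window)
  ), class = "block_spec")
}

#' Specify a full task design
#'
#' The default design has 11 blocks with set sizes drawn from 2 to 5 and
#' three response options; feedback is deterministic. Timing constants are
#' recorded for reference (fixation 0.5 s, response window 7 s, feedback
#' 0.75 s); only the 7 s response ceiling affects simulation.
#'
#' @param n_blocks Number of blocks.
#' @param set_size_sequence Integer vector of per-block set sizes, each in
#'   2 to 5; length `n_blocks`.
#' @param n_actions Number of response options (fixed at 3).
#' @param min_presentations,max_presentations,criterion_hits,criterion_window
#'   Passed to every [block_spec()].
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_blocks = 11L,
                        set_size_sequence = c(2, 2, 3, 3, 3, 4, 4, 4, 5, 5, 4),
                        n_actions = 3L,
                        min_presentations = 9L, max_presentations = 15L,
                        criterion_hits = 4L, criterion_window = 5L) {
  n_blocks <- as.integer(n_blocks)
  set_size_sequence <- as.integer(set_size_sequence)
  if (length(set_size_sequence) != n_blocks)
    stop("set_size_sequence must have length n_blocks")
  if (any(set_size_sequence < 2L | set_size_sequence > 5L))
    stop("every set size must be between 2 and 5")
  if (n_actions != 3L) stop("n_actions is fixed at 3")
  structure(list(
    n_blocks = n_blocks,
    set_size_sequence = set_size_sequence,
    n_actions = 3L,
    min_presentations = as.integer(min_presentations),
    max_presentations = as.integer(max_presentations),
    criterion_hits = as.integer(criterion_hits),
    criterion_window = as.integer(criterion_window),
    timing = c(fixation = 0.5, max_stimulus = 7, feedback = 0.75)
  ), class = "design_spec")
}

#' Instantiate the blocks of a design
#'
#' Draws a random (seeded) stimulus-to-action map for every block. Maps are
#' sampled uniformly subject to covering at least two distinct actions:
#' stimuli may share an action, but a block whose every stimulus requires the
#' same response would be degenerate (a single motor rule with no
#' stimulus-response mapping to learn), so such maps are excluded.
#'
#' @param design A [design_spec()].
#' @param seed Integer seed for the action-map draws.
#' @return List of [block_spec()] objects.
#' @export
make_design <- function(design, seed = 1L) {
  stopifnot(inherits(design, "design_spec"))
  rng <- local_rng(seed)
  lapply(seq_len(design$n_blocks), function(b) {
    ns <- design$set_size_sequence[b]
    repeat {
      ca <- sample(1:3, ns, replace = TRUE)
      if (length(unique(ca)) >= 2L) break
    }
    block_spec(
      block_index = b, set_size = ns,
      stimulus_ids = sprintf("b%d_s%d", b, seq_len(ns)),
      correct_action = ca,
      min_presentations = design$min_presentations,
      max_presentations = design$max_presentations,
      criterion_hits = design$criterion_hits,
      criterion_window = design$criterion_window
    )
  })
}

# Seed the RNG for a stage. Stage names are hashed into an offset so that
# pipeline stages driven by one global seed draw independent streams.
local_rng <- function(seed, stage = NULL) {
  seed <- as.integer(seed)
  if (!is.null(stage)) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    seed <- (seed + 7919L * (h %% 262139L)) %% .Machine$integer.max
  }
  set.seed(seed)
  invisible(seed)
}

#' Administer one block under the adaptive stopping rule
#'
#' Presents stimuli in pseudo-randomized order (uniform among the still-active
#' stimuli, never repeating the immediately preceding stimulus while two or
#' more stimuli remain active) and queries `responder` for an action on each
#' trial. A stimulus is retired at the first presentation count of at least
#' `min_presentations` at which it was answered correctly on at least 4 of its
#' last 5 presentations, and unconditionally at `max_presentations`.
#'
#' @param spec A [block_spec()].
#' @param responder A function `function(stimulus, trial)` returning an action
#'   in `1:3`. `trial` is the upcoming row of the block table (list with
#'   `stimulus`, `presentation_index`, `block`, `set_size`), so stateful
#'   learners can key on it; simple responders may ignore it.
#' @param seed Integer seed for the presentation order.
#' @param subject Subject identifier stored in the output.
#' @param rt_fun Optional `function(stimulus, action)` returning a response
#'   time in seconds; defaults to `NA` RTs (behavioral simulators supply RTs
#'   from the accumulator race instead).
#' @return A data.frame of trial records in presentation order, with columns
#'   `subject, block, set_size, stimulus, presentation_index, action,
#'   correct_action, reward, rt`.
#' @export
run_block <- function(spec, responder, seed = 1L, subject = "sim",
                      rt_fun = NULL) {
  stopifnot(inherits(spec, "block_spec"))
  if (length(spec$stimulus_ids) == 0L) stop("empty stimulus set")
  local_rng(seed)
  run_block_impl(spec, responder, subject, rt_fun)
}

# Core loop, uses the current RNG state (callers manage seeding).
run_block_impl <- function(spec, responder, subject = "sim", rt_fun = NULL) {
  ids <- spec$stimulus_ids
  n_s <- length(ids)
  count <- stats::setNames(integer(n_s), ids)
  history <- stats::setNames(vector("list", n_s), ids) # correctness per stim
  active <- ids
  last <- NA_character_
  rows <- list()
  t_idx <- 0L
  while (length(active) > 0L) {
    pool <- active
    if (length(active) >= 2L && !is.na(last)) pool <- setdiff(pool, last)
    stim <- if (length(pool) == 1L) pool else sample(pool, 1L)
    t_idx <- t_idx + 1L
    count[stim] <- count[stim] + 1L
    trial <- list(stimulus = stim, presentation_index = count[[stim]],
                  block = spec$block_index, set_size = spec$set_size)
    action <- as.integer(responder(stim, trial))
    if (length(action) != 1L || is.na(action) || !action %in% 1:3)
      stop("responder returned an action outside 1:3")
    correct <- spec$correct_action[[stim]]
    reward <- as.integer(action == correct)
    history[[stim]] <- c(history[[stim]], reward)
    rt <- if (is.null(rt_fun)) NA_real_ else rt_fun(stim, action)
    rows[[t_idx]] <- data.frame(
      subject = subject, block = spec$block_index, set_size = spec$set_size,
      stimulus = stim, presentation_index = count[[stim]],
      action = action, correct_action = correct, reward = reward, rt = rt,
      stringsAsFactors = FALSE)
    # retirement check
    h <- history[[stim]]
    k <- count[[stim]]
    if (k >= spec$max_presentations) {
      active <- setdiff(active, stim)
    } else if (k >= spec$min_presentations) {
      w <- utils::tail(h, spec$criterion_window)
      if (sum(w) >= spec$criterion_hits) active <- setdiff(active, stim)
    }
    last <- stim
  }
  do.call(rbind, rows)
}

#' Compute the delay covariate
#'
#' Delay is the number of trials (of any stimulus) since the most recent trial
#' on which the same stimulus was answered correctly, within a block. It is
#' `NA` on a stimulus's first presentation and whenever no prior correct
#' response to that stimulus exists. Trials must be in presentation order
#' within each subject-block.
#'
#' @param trials Trial data.frame with columns `subject, block, stimulus,
#'   presentation_index, reward`.
#' @return `trials` with a `delay` column added (integer, `NA` when undefined).
#' @export
compute_delay <- function(trials) {
  req <- c("subject", "block", "stimulus", "presentation_index", "reward")
  if (!all(req %in% names(trials))) stop("missing required columns")
  trials$delay <- NA_integer_
  grp <- interaction(trials$subject, trials$block, drop = TRUE)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    last_correct <- list()
    for (j in seq_along(idx)) {
      i <- idx[j]
      s <- trials$stimulus[i]
      pi_expect <- sum(trials$stimulus[idx[seq_len(j)]] == s)
      if (pi_expect != trials$presentation_index[i])
        stop("trials are not in presentation order")
      if (!is.null(last_correct[[s]]))
        trials$delay[i] <- j - last_correct[[s]]
      if (trials$reward[i] == 1L) last_correct[[s]] <- j
    }
  }
  trials
}

#' Flag trials enterable into EEG analyses
#'
#' Retains only correct trials beyond a stimulus's first presentation, the
#' trial set the single-trial ERP analyses operate on, and flags them in an
#' `included_in_eeg` column.
#'
#' @param trials Trial data.frame with `reward` and `presentation_index`.
#' @return `trials` with logical column `included_in_eeg` added.
#' @export
eeg_trial_filter <- function(trials) {
  trials$included_in_eeg <- trials$reward == 1L & trials$presentation_index >= 2L
  trials
}

#' Dataset-exclusion arithmetic
#'
#' @param n_total Total number of datasets (or trials) before exclusion.
#' @param n_excluded Number excluded.
#' @return An object of class `qc_report` with fields `n_total`, `n_excluded`,
#'   `n_retained`, `exclusion_rate_pct` (one decimal) and `retained_fraction`.
#' @export
qc_report <- function(n_total, n_excluded) {
  n_total <- as.integer(n_total); n_excluded <- as.integer(n_excluded)
  if (n_total <= 0L) stop("n_total must be positive")
  if (n_excluded < 0L || n_excluded > n_total)
    stop("n_excluded must lie in [0, n_total]")
  structure(list(
    n_total = n_total,
    n_excluded = n_excluded,
    n_retained = n_total - n_excluded,
    exclusion_rate_pct = round(100 * n_excluded / n_total, 1),
    retained_fraction = (n_total - n_excluded) / n_total
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d of %d datasets excluded (%.1f%%), %d retained\n",
              x$n_excluded, x$n_total, x$exclusion_rate_pct, x$n_retained))
  invisible(x)
}
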