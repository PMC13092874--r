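#' Write / read a trial table as TSV
#'
#' Tab-separated, one row per trial; a missing delay is written as an empty
#' field. Round-trips all task and latent columns.
#'
#' @param trials Trial data.frame.
#' @param path File path.
#' @return `read_trial_table` returns the data.frame; `write_trial_table`
#'   returns `path` invisibly.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  out <- utils::read.delim(path, sep = "\t", na.strings = "",
                           stringsAsFactors = FALSE)
  if ("included_in_eeg" %in% names(out))
    out$included_in_eeg <- as.logical(out$included_in_eeg)
  out
}

#' Write / read a design configuration as YAML
#'
#' Serializes the block structure, stopping-rule settings and seed of a task
#' design.
#'
#' @param design A [design_spec()].
#' @param path File path.
#' @param seed Seed recorded alongside the design.
#' @return `read_design_config` returns a list with `design` (a
#'   [design_spec()]) and `seed`.
#' @export
write_design_config <- function(design, path, seed = 1L) {
  stopifnot(inherits(design, "design_spec"))
  yaml::write_yaml(list(
    n_blocks = design$n_blocks,
    set_size_sequence = design$set_size_sequence,
    min_presentations = design$min_presentations,
    max_presentations = design$max_presentations,
    criterion = list(hits = design$criterion_hits,
                     window = design$criterion_window),
    seed = as.integer(seed)), path)
  invisible(path)
}

#' @rdname write_design_config
#' @export
read_design_config <- function(path) {
  y <- yaml::read_yaml(path)
  list(design = design_spec(
    n_blocks = y$n_blocks, set_size_sequence = y$set_size_sequence,
    min_presentations = y$min_presentations,
    max_presentations = y$max_presentations,
    criterion_hits = y$criterion$hits,
    criterion_window = y$criterion$window), seed = y$seed)
}

#' Write / read an epoch set as text
#'
#' Text serialization of an [epoch_set()]: `<prefix>.json` holds the header
#' (times, channels, sampling rate, lock, trial index, dimensions) and
#' `<prefix>.tsv` the voltages, one row per trial-channel pair and one column
#' per sample.
#'
#' @param epochs An [epoch_set()].
#' @param prefix Path prefix (without extension).
#' @return `read_epochs` returns the reconstructed [epoch_set()].
#' @export
write_epochs <- function(epochs, prefix) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  jsonlite::write_json(list(
    times = epochs$times, channels = epochs$channels,
    sampling_rate = epochs$sampling_rate, lock = epochs$lock,
    trial_index = epochs$trial_index, dim = d),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)), nrow = d[1] * d[2],
                 byrow = TRUE)
  utils::write.table(flat, paste0(prefix, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(prefix) {
  hdr <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.delim(paste0(prefix, ".tsv"), header = FALSE,
                                      sep = "\t"))
  d <- hdr$dim
  data <- aperm(array(t(flat), c(d[3], d[2], d[1])), c(3, 2, 1))
  epoch_set(data, hdr$times, hdr$channels, hdr$sampling_rate, hdr$lock,
            hdr$trial_index)
}

#' Serialize a fit's scalar results
#'
#' Writes the group posterior summary, per-subject MAP estimates and
#' diagnostics as JSON, and the per-subject posterior draws as CSV.
#'
#' @param fit An [rlwm_lba()] fit.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fit_result <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- summary(fit)
  jsonlite::write_json(list(
    model_tag = fit$model_tag, mode = fit$mode, seed = fit$seed,
    n_trials = fit$n_trials, loglik_map = sum(fit$loglik_map),
    group = fit$group, convergence = unname(s$convergence)),
    file.path(dir, "fit.json"), auto_unbox = TRUE, digits = NA)
  draws <- do.call(rbind, lapply(names(fit$subject_fits), function(nm)
    data.frame(subject = nm, fit$subject_fits[[nm]]$draws)))
  utils::write.csv(draws, file.path(dir, "draws.csv"), row.names = FALSE)
  invisible(dir)
}

#' Export a group statistical map as long-format TSV
#'
#' One row per predictor, channel and time point with the trimmed-mean beta,
#' Yuen t, p-value and Bonferroni significance flag.
#'
#' @param stat_map A [group_inference()] result.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_stat_map_tsv <- function(stat_map, path) {
  stopifnot(inherits(stat_map, "group_stat_map"))
  d <- dim(stat_map$t)
  preds <- dimnames(stat_map$t)[[1]]
  grid <- expand.grid(predictor = preds,
                      channel = stat_map$channels,
                      time_ms = stat_map$times,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$tmean <- as.vector(stat_map$tmean)
  grid$t <- as.vector(stat_map$t)
  grid$p <- as.vector(stat_map$p)
  grid$significant <- as.vector(stat_map$mask)
  utils::write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
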