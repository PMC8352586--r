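# Delimited-text I/O with schema validation.
#
# Trials: CSV with header, one row per trial. Spikes: long CSV with one row
# per spike. Events: one row per correct trial. All times are seconds in
# the trial table (decimal point) and integer-precision milliseconds
# relative to cue onset in the spike/event tables.

TRIAL_COLUMNS <- c("session_id", "trial_index", "reward_size", "delay_class",
                   "delay_mean_s", "outcome", "is_repeat", "cum_reward_drops",
                   "rcum", "treatment")
OUTCOME_LEVELS <- c("correct", "early", "late")
TREATMENT_LEVELS <- c("baseline", "control", "inactivation")

#' Read and validate a trial table
#'
#' @param path CSV file with columns `session_id`, `trial_index` (0-based
#'   within session), `reward_size`, `delay_class`, `delay_mean_s`,
#'   `outcome`, `is_repeat`, `cum_reward_drops`, `rcum`, `treatment`; extra
#'   columns (event times) are kept.
#' @return validated data frame of trials.
#' @export
read_trials <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(TRIAL_COLUMNS, names(tr))
  if (length(miss)) stopf("%s: missing column(s) %s", path,
                          paste(miss, collapse = ", "))
  bad <- which(!tr$outcome %in% OUTCOME_LEVELS)
  if (length(bad)) stopf("%s: unknown outcome '%s' at data row %d", path,
                         tr$outcome[bad[1]], bad[1])
  bad <- which(!tr$treatment %in% TREATMENT_LEVELS)
  if (length(bad)) stopf("%s: unknown treatment '%s' at data row %d", path,
                         tr$treatment[bad[1]], bad[1])
  bad <- which(tr$rcum < 0 | tr$rcum > 1)
  if (length(bad)) stopf("%s: rcum outside [0,1] at data row %d", path, bad[1])
  bad <- which(tr$reward_size < 1)
  if (length(bad)) stopf("%s: reward_size < 1 at data row %d", path, bad[1])
  tr
}

#' Write a trial table
#'
#' @param trials data frame with at least the [read_trials()] schema.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  miss <- setdiff(TRIAL_COLUMNS, names(trials))
  if (length(miss)) stopf("trials lack column(s) %s", paste(miss, collapse = ", "))
  write.csv(trials, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write spike and event tables for a neuron population
#'
#' @param population list of [spike_data()] objects.
#' @param spikes_path,events_path output CSV paths. The spike table has
#'   columns `neuron_id`, `session_id`, `trial_index`, `spike_time_ms`; the
#'   event table has `neuron_id`, `session_id`, `trial_index`, `cue_ms`,
#'   `go_ms`, `release_ms`, `reward_ms`.
#' @return invisibly, the two paths.
#' @export
write_spikes <- function(population, spikes_path, events_path) {
  sp <- do.call(rbind, lapply(population, function(sd_) {
    k <- lengths(sd_$spikes)
    data.frame(neuron_id = sd_$neuron_id,
               session_id = rep(sd_$meta$session_id, k),
               trial_index = rep(sd_$events$trial_index, k),
               spike_time_ms = unlist(sd_$spikes))
  }))
  ev <- do.call(rbind, lapply(population, function(sd_) {
    data.frame(neuron_id = sd_$neuron_id, session_id = sd_$meta$session_id,
               trial_index = sd_$events$trial_index, cue_ms = 0,
               go_ms = sd_$events$go_ms, release_ms = sd_$events$release_ms,
               reward_ms = sd_$events$reward_ms)
  }))
  write.csv(sp, spikes_path, row.names = FALSE, quote = FALSE, na = "")
  write.csv(ev, events_path, row.names = FALSE, quote = FALSE, na = "")
  invisible(c(spikes = spikes_path, events = events_path))
}

#' Read spike and event tables into spike_data objects
#'
#' @param spikes_path,events_path CSVs as written by [write_spikes()].
#' @param trials optional trial table supplying per-trial metadata
#'   (condition, `rcum`) matched on `session_id` + `trial_index`.
#' @param dv_k optional discount rate; when given, a `dv` column is added
#'   to each neuron's metadata.
#' @return named list of [spike_data()] objects (one per `neuron_id`).
#' @export
read_spikes <- function(spikes_path, events_path, trials = NULL, dv_k = NULL) {
  sp <- read.csv(spikes_path, stringsAsFactors = FALSE)
  ev <- read.csv(events_path, stringsAsFactors = FALSE)
  for (cn in c("neuron_id", "trial_index", "spike_time_ms")) {
    if (!cn %in% names(sp)) stopf("%s: missing column %s", spikes_path, cn)
  }
  out <- lapply(split(ev, ev$neuron_id), function(e) {
    e <- e[order(e$trial_index), ]
    s <- sp[sp$neuron_id == e$neuron_id[1], ]
    spk <- lapply(e$trial_index, function(ti) {
      x <- s$spike_time_ms[s$trial_index == ti]
      if (is.unsorted(x)) stopf("%s: unsorted spike times for neuron %s trial %d",
                                spikes_path, e$neuron_id[1], ti)
      x
    })
    meta <- data.frame(session_id = e$session_id, trial_index = e$trial_index)
    if (!is.null(trials)) {
      m <- match(paste(e$session_id, e$trial_index),
                 paste(trials$session_id, trials$trial_index))
      if (anyNA(m)) stopf("event rows without matching trials (first: neuron %s trial %d)",
                          e$neuron_id[1], e$trial_index[which(is.na(m))[1]])
      meta <- cbind(meta, trials[m, c("reward_size", "delay_class",
                                      "delay_mean_s", "rcum")])
      if (!is.null(dv_k)) {
        meta$dv <- discounted_value(meta$reward_size, meta$delay_mean_s, dv_k)
      }
    }
    rownames(meta) <- NULL
    spike_data(e$neuron_id[1], spk,
               e[, c("trial_index", "go_ms", "release_ms", "reward_ms")],
               meta)
  })
  out
}

#' Export a discounting fit as a JSON record
#'
#' @param fit a [fit_discount_model()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  getp <- function(nm) if (nm %in% names(fit$params)) unname(fit$params[[nm]]) else 0
  rec <- list(model_name = fit$model, k = getp("k"), a = getp("a"),
              lambda = getp("lambda"), ssr = fit$ssr,
              r_squared = fit$r_squared, n_points = fit$n_points)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
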