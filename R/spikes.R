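# Container for event-aligned spike timestamps of one neuron.

#' Spike data for one neuron
#'
#' Bundles per-trial spike timestamps (ms relative to cue onset), per-trial
#' event times, and the trial metadata needed for regression (condition,
#' normalized cumulative reward, discounted value).
#'
#' @param neuron_id character id.
#' @param spikes list with one sorted numeric vector of timestamps (ms,
#'   relative to cue onset) per trial.
#' @param events data frame with columns `trial_index`, `go_ms`,
#'   `release_ms`, `reward_ms` (ms relative to cue onset; only correct
#'   trials belong here).
#' @param meta data frame aligned with `spikes` carrying at least
#'   `reward_size`, `delay_class`, `delay_mean_s`; typically also `rcum`
#'   and `dv`.
#' @param coding_class optional ground-truth label (synthetic data only).
#' @return object of class `spike_data`.
#' @export
spike_data <- function(neuron_id, spikes, events, meta, coding_class = NA) {
  if (length(spikes) != nrow(events) || length(spikes) != nrow(meta)) {
    stopf("spikes, events and meta must describe the same trials")
  }
  unsorted <- vapply(spikes, is.unsorted, logical(1))
  if (any(unsorted)) stopf("spike timestamps unsorted in trial %d",
                           which(unsorted)[1])
  structure(list(neuron_id = neuron_id, spikes = spikes, events = events,
                 meta = meta, coding_class = coding_class),
            class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf("spike_data %s: %d trials, %d spikes%s\n", x$neuron_id,
              length(x$spikes), sum(lengths(x$spikes)),
              if (!is.na(x$coding_class)) paste0(" [", x$coding_class, "]") else ""))
  invisible(x)
}

n_trials <- function(sd) length(sd$spikes)

# Spike times re-aligned to a task event (ms). Trials lacking the event are
# dropped (with their metadata) for release/reward alignment.
align_spikes <- function(sd, event = c("cue", "release", "reward")) {
  event <- match.arg(event)
  if (event == "cue") return(sd)
  col <- paste0(event, "_ms")
  shift <- sd$events[[col]]
  keep <- is.finite(shift)
  spikes <- Map(function(s, d) s - d, sd$spikes[keep], shift[keep])
  spike_data(sd$neuron_id, spikes, sd$events[keep, , drop = FALSE],
             sd$meta[keep, , drop = FALSE], sd$coding_class)
}

# Per-trial spike counts in [lo, hi) ms for an aligned spike_data.
window_counts <- function(spikes, lo, hi) {
  vapply(spikes, function(s) sum(s >= lo & s < hi), numeric(1))
}
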