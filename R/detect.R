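# Sliding-window chi-square detection of event-locked responses.
#
# For each 100 ms test window (stepped in 10 ms increments over an
# event-specific range) the proportion of filled (>= 1 spike) to empty 1 ms
# bins, pooled across trials, is compared with the proportion in the 500 ms
# pre-cue background window by a 2x2 Pearson chi-square (1 df, no
# continuity correction). Responsiveness additionally requires the test
# proportion to exceed background (responses are elevations).

default_search_range <- function(event) {
  switch(event, cue = c(0, 1500), release = c(-300, 300), reward = c(0, 500))
}

# Pooled filled-bin counts per 1 ms bin over [lo, hi): entry b is the number
# of trials whose bin b contains at least one spike.
pooled_filled <- function(spikes, lo, hi) {
  nb <- hi - lo
  counts <- integer(nb)
  for (s in spikes) {
    b <- unique(floor(s[s >= lo & s < hi])) - lo + 1L
    counts[b] <- counts[b] + 1L
  }
  counts
}

chisq_2x2 <- function(f1, n1, f2, n2) {
  # Pearson chi-square on [f1, n1-f1; f2, n2-f2], vectorized over f1
  tot <- n1 + n2
  fc <- f1 + f2
  ec <- tot - fc
  stat <- tot * (f1 * (n2 - f2) - (n1 - f1) * f2)^2 /
    (as.double(fc) * ec * n1 * n2)
  stat[fc == 0 | ec == 0] <- 0
  pchisq(stat, df = 1, lower.tail = FALSE)
}

run_starts <- function(sig, min_run) {
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  i <- which(r$values & r$lengths >= min_run)
  if (!length(i)) return(integer(0))
  ends[i] - r$lengths[i] + 1L
}

#' Detect an event-locked response by sliding chi-square tests
#'
#' The background is the 500 ms window before cue onset. The test window
#' spans `window_ms` and moves in `step_ms` increments over the
#' event-specific search range (cue: 0-1500 ms; release: -300 to 300 ms;
#' reward: 0-500 ms). The response start is the middle of the first of four
#' consecutive significant windows; the end is the middle of the last
#' significant window in the block reachable from the onset run without a
#' gap of four or more consecutive non-significant windows. A neuron is
#' responsive when at least five consecutive windows are significant.
#'
#' @param sd a [spike_data()].
#' @param event `"cue"`, `"release"`, or `"reward"`.
#' @param alpha per-window significance level.
#' @param window_ms,step_ms test-window span and increment, ms.
#' @param search_range two-element ms range; default depends on `event`.
#' @param background ms range of the pre-cue background window.
#' @return object of class `response_window`: `event`, `start_ms`,
#'   `end_ms`, `duration_ms`, `is_responsive`, `window_mid_ms`,
#'   `p_values`, `significant`.
#' @export
detect_response <- function(sd, event = c("cue", "release", "reward"),
                            alpha = 0.05, window_ms = 100, step_ms = 10,
                            search_range = NULL,
                            background = c(-500, 0)) {
  event <- match.arg(event)
  if (n_trials(sd) < 1) stopf("no trials")
  if (background[2] <= background[1]) stopf("empty background window")
  if (is.null(search_range)) search_range <- default_search_range(event)

  nt_bg <- n_trials(sd)
  f_bg <- sum(pooled_filled(sd$spikes, background[1], background[2]))
  n_bg <- (background[2] - background[1]) * nt_bg

  al <- align_spikes(sd, event)
  nt <- n_trials(al)
  if (nt < 1) stopf("no trials carry event '%s'", event)
  lo <- search_range[1]; hi <- search_range[2]
  filled <- pooled_filled(al$spikes, lo, hi)
  cum <- c(0L, cumsum(filled))
  starts <- seq(lo, hi - window_ms, by = step_ms)
  f_test <- cum[starts - lo + window_ms + 1L] - cum[starts - lo + 1L]
  n_test <- window_ms * nt

  p <- chisq_2x2(f_test, n_test, f_bg, n_bg)
  elevated <- f_test / n_test > f_bg / n_bg
  sig <- p < alpha & elevated
  mids <- starts + window_ms / 2

  onset_runs <- run_starts(sig, 4L)
  if (!length(onset_runs)) {
    res <- list(start_ms = NA_real_, end_ms = NA_real_, duration_ms = 0,
                is_responsive = FALSE)
  } else {
    first <- onset_runs[1]
    # extend forward, tolerating gaps shorter than 4 non-significant windows
    last_sig <- first
    gap <- 0L
    for (j in seq(first, length(sig))) {
      if (sig[j]) { last_sig <- j; gap <- 0L } else {
        gap <- gap + 1L
        if (gap >= 4L) break
      }
    }
    res <- list(start_ms = mids[first], end_ms = mids[last_sig],
                duration_ms = mids[last_sig] - mids[first],
                is_responsive = length(run_starts(sig, 5L)) > 0)
  }
  structure(c(list(event = event), res,
              list(window_mid_ms = mids, p_values = p, significant = sig,
                   alpha = alpha)),
            class = "response_window")
}

#' @export
print.response_window <- function(x, ...) {
  if (is.na(x$start_ms)) {
    cat(sprintf("%s: no response detected\n", x$event))
  } else {
    cat(sprintf("%s response: [%g, %g] ms (duration %g ms)%s\n", x$event,
                x$start_ms, x$end_ms, x$duration_ms,
                if (x$is_responsive) "" else " [below responsiveness rule]"))
  }
  invisible(x)
}

#' Per-trial firing rate in a detected response window
#'
#' Counts spikes in the half-open interval `[start_ms, end_ms)` of the
#' window's alignment and divides by its duration.
#'
#' @param sd a [spike_data()].
#' @param window a [detect_response()] result (or a list with `event`,
#'   `start_ms`, `end_ms`).
#' @return numeric vector of rates in spikes/s, one per (aligned) trial.
#' @export
response_rate <- function(sd, window) {
  if (is.na(window$start_ms) || window$end_ms <= window$start_ms) {
    stopf("empty or zero-duration response window")
  }
  al <- align_spikes(sd, window$event)
  counts <- window_counts(al$spikes, window$start_ms, window$end_ms)
  1000 * counts / (window$end_ms - window$start_ms)
}
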