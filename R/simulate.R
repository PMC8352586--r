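# Synthetic task sessions and spike trains.
#
# The generator states the world the analyses assume: six size-by-delay
# conditions drawn uniformly with repeat-on-error, Bernoulli errors from the
# discounting model with satiation in the value, and low-baseline Poisson
# neurons whose cue response is linear in the discounted value.

#' Task specification
#'
#' @param task `"delayed"` (sizes `{1, large_drops}` crossed with delays
#'   0.3 +/- 0.1, 3.3 +/- 0.6, 6.9 +/- 1.2 s) or `"rewardsize"` (sizes
#'   1, 2, 4, 8 drops, all delivered at 0.3 +/- 0.1 s).
#' @param large_drops drops in the large reward of the delayed task (3 or 4,
#'   subject-dependent).
#' @param wait_range cue-to-go interval range in seconds (uniform draw).
#' @param response_window allowed bar-release window after go, seconds.
#' @param iti_s inter-trial interval, seconds.
#' @param repeat_on_error re-present the same condition after an error?
#' @return a `task_spec` list with a `conditions` data frame
#'   (`reward_size`, `delay_class`, `delay_mean_s`, `delay_jitter_s`).
#' @export
task_spec <- function(task = c("delayed", "rewardsize"), large_drops = 3,
                      wait_range = c(1.0, 2.0),
                      response_window = c(0.2, 1.0), iti_s = 1.0,
                      repeat_on_error = TRUE) {
  task <- match.arg(task)
  conditions <- if (task == "delayed") {
    data.frame(
      reward_size = rep(c(1, large_drops), each = 3),
      delay_class = rep(c("immediate", "short", "long"), 2),
      delay_mean_s = rep(c(0.3, 3.3, 6.9), 2),
      delay_jitter_s = rep(c(0.1, 0.6, 1.2), 2))
  } else {
    data.frame(reward_size = c(1, 2, 4, 8), delay_class = "immediate",
               delay_mean_s = 0.3, delay_jitter_s = 0.1)
  }
  stopifnot(response_window[1] < response_window[2],
            all(conditions$delay_jitter_s <= conditions$delay_mean_s))
  structure(list(task = task, conditions = conditions,
                 wait_range = wait_range, response_window = response_window,
                 iti_s = iti_s, repeat_on_error = repeat_on_error),
            class = "task_spec")
}

#' Behavioral generator parameters
#'
#' @param k,a,lambda generating discounting/satiation parameters (see
#'   [error_rate_with_satiation()]).
#' @param early_fraction proportion of errors that are early releases.
#' @param n_correct stop rule: session ends after this many correct trials
#'   (the usual recording block is 120).
#' @param max_trials hard cap on total trials (guards impossible stop rules).
#' @param satiation_form placement of the satiation factor used for the
#'   Bernoulli error draw; the value-placed default makes errors rise with
#'   cumulative reward.
#' @param early_timing mean and sd (seconds after cue) of the truncated
#'   Gaussian from which early-release times are drawn; the default peak at
#'   1.2 s sits inside the observed 0.7-1.8 s range.
#' @param p_error_max ceiling on the generative Bernoulli error probability.
#'   The discounting model can predict rates at the clip boundary 1 for
#'   harsh conditions; with repeat-on-error a certain error would re-present
#'   the same condition forever. Real behavior retains occasional correct
#'   responses even when motivation is minimal, so the generator keeps a
#'   5% success floor by default (see the methods vignette).
#' @param init_time_s baseline trial-initiation time (previous reward to
#'   lever grip), seconds.
#' @param init_time_gain proportional slowing of initiation with `rcum`
#'   (initiation time scales by `1 + gain * rcum`).
#' @param seed integer seed; byte-identical output under the same seed.
#' @return a `behavior_gen_params` list.
#' @export
behavior_gen_params <- function(k = 0.2, a = 2, lambda = 1,
                                early_fraction = 0.5, n_correct = 120,
                                max_trials = 5000,
                                satiation_form = c("value", "printed"),
                                early_timing = c(mean = 1.2, sd = 0.5),
                                init_time_s = 3, init_time_gain = 0.3,
                                p_error_max = 0.95, seed = 1L) {
  check_number(k, "k", lower = 0); check_number(a, "a", lower = 1e-12)
  check_number(lambda, "lambda", lower = 0)
  check_number(early_fraction, "early_fraction", 0, 1)
  check_number(p_error_max, "p_error_max", 0, 1)
  structure(list(k = k, a = a, lambda = lambda,
                 early_fraction = early_fraction, n_correct = n_correct,
                 max_trials = max_trials,
                 satiation_form = match.arg(satiation_form),
                 early_timing = early_timing, init_time_s = init_time_s,
                 init_time_gain = init_time_gain,
                 p_error_max = p_error_max, seed = as.integer(seed)),
            class = "behavior_gen_params")
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  for (i in 1:50) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  runif(1, lo, hi)   # pathological bounds: fall back to uniform
}

#' Generate one synthetic task session
#'
#' Runs the task trial by trial: the condition is drawn uniformly (or
#' repeated after an error when the task repeats on error), the outcome is
#' Bernoulli with error probability given by the satiation-extended
#' discounting model evaluated at the current satiation state, and full
#' event times (cue, go, release, reward) are emitted for the spike
#' generator. Reward is delivered only on correct trials; the session stops
#' after `gen$n_correct` correct trials.
#'
#' The written `rcum` column is the cumulative delivered reward *including*
#' the current trial, normalized by the realized session total, so it is
#' nondecreasing and ends at exactly 1. The Bernoulli draw uses the
#' pre-trial state normalized by the expected total (the realized total is
#' unknown mid-session).
#'
#' @param task a [task_spec()].
#' @param gen a [behavior_gen_params()].
#' @param session_id character id stored in the table.
#' @param treatment label stored in the table (`"baseline"`, `"control"`,
#'   or `"inactivation"`).
#' @return data frame of trials (one row per trial) with the schema of
#'   [read_trials()] plus event-time columns `go_s`, `release_s`,
#'   `reward_s`, `init_time_s` (seconds from cue onset; `NA` where the
#'   event did not occur).
#' @export
generate_session <- function(task, gen, session_id = "s1",
                             treatment = "baseline") {
  stopifnot(inherits(task, "task_spec"), inherits(gen, "behavior_gen_params"))
  conds <- task$conditions
  ncond <- nrow(conds)
  expected_total <- gen$n_correct * mean(conds$reward_size)
  with_seed(gen$seed, {
    N <- gen$max_trials
    v_ci <- integer(N); v_rep <- integer(N); v_out <- character(N)
    v_cum <- numeric(N); v_go <- numeric(N); v_rel <- numeric(N)
    v_rew <- numeric(N); v_init <- numeric(N)
    n_corr <- 0L; drops <- 0; t <- 0L; repeat_cond <- NA_integer_
    while (n_corr < gen$n_correct && t < N) {
      t <- t + 1L
      is_rep <- task$repeat_on_error && !is.na(repeat_cond)
      ci <- if (is_rep) repeat_cond else sample.int(ncond, 1)
      rcum_state <- min(1, drops / expected_total)
      p_err <- min(gen$p_error_max, error_rate_with_satiation(
        conds$reward_size[ci], conds$delay_mean_s[ci], rcum_state,
        gen$k, gen$a, gen$lambda, form = gen$satiation_form))
      err <- runif(1) < p_err
      wait <- runif(1, task$wait_range[1], task$wait_range[2])
      delay <- conds$delay_mean_s[ci] +
        runif(1, -conds$delay_jitter_s[ci], conds$delay_jitter_s[ci])
      init <- if (t == 1L) NA_real_ else {
        gen$init_time_s * (1 + gen$init_time_gain * rcum_state) *
          exp(rnorm(1, 0, 0.2))
      }
      if (!err) {
        rt <- rtruncnorm1(0.35, 0.06, task$response_window[1] + 0.01,
                          task$response_window[2] - 0.01)
        release <- wait + rt
        reward <- release + delay
        outcome <- "correct"
        n_corr <- n_corr + 1L
        drops <- drops + conds$reward_size[ci]
        repeat_cond <- NA_integer_
      } else {
        if (runif(1) < gen$early_fraction) {
          outcome <- "early"
          release <- rtruncnorm1(gen$early_timing[["mean"]],
                                 gen$early_timing[["sd"]],
                                 0.1, wait + task$response_window[1] - 0.01)
        } else {
          outcome <- "late"
          release <- NA_real_
        }
        reward <- NA_real_
        repeat_cond <- ci
      }
      v_ci[t] <- ci; v_rep[t] <- as.integer(is_rep); v_out[t] <- outcome
      v_cum[t] <- drops   # includes this trial's delivery
      v_go[t] <- wait; v_rel[t] <- release; v_rew[t] <- reward
      v_init[t] <- init
    }
    if (n_corr < gen$n_correct) {
      warning("stop rule not reached; session capped at ", t, " trials")
    }
    i <- seq_len(t)
    total <- if (drops > 0) drops else 1
    data.frame(
      session_id = session_id, trial_index = i - 1L,
      reward_size = conds$reward_size[v_ci[i]],
      delay_class = conds$delay_class[v_ci[i]],
      delay_mean_s = conds$delay_mean_s[v_ci[i]],
      outcome = v_out[i], is_repeat = v_rep[i],
      cum_reward_drops = v_cum[i], rcum = v_cum[i] / total,
      treatment = treatment, go_s = v_go[i], release_s = v_rel[i],
      reward_s = v_rew[i], init_time_s = v_init[i])
  })
}

#' Generate several sessions with deterministic per-session sub-seeds
#'
#' @inheritParams generate_session
#' @param n_sessions number of sessions.
#' @param seed parent seed; session `i` runs under a deterministic child
#'   seed so the collection is reproducible as a whole.
#' @param ... passed to [behavior_gen_params()].
#' @return data frame of all sessions' trials, `session_id` = `"s1"`...
#' @export
generate_sessions <- function(task, n_sessions, seed = 1L,
                              treatment = "baseline", ...) {
  out <- lapply(seq_len(n_sessions), function(i) {
    gen <- behavior_gen_params(..., seed = child_seed(seed, i))
    generate_session(task, gen, session_id = paste0("s", i),
                     treatment = treatment)
  })
  do.call(rbind, out)
}

#' Neuron generator parameters
#'
#' @param baseline_rate spontaneous rate in spikes/s (striatal projection
#'   neurons discharge below 2 spikes/s).
#' @param beta0,betaV cue-response intercept and discounted-value slope in
#'   spikes/s (per drop-equivalent for `betaV`); the instantaneous cue
#'   response is `max(0, beta0 + betaV * DV)` on top of baseline.
#' @param kernel named vector `onset`, `rise`, `duration` (ms): the cue
#'   response ramps up over `rise` ms starting `onset` ms after the cue and
#'   lasts `duration` ms in total.
#' @param coding_class one of `"positive_dv"`, `"negative_dv"`,
#'   `"non_dv_visual"`, `"unresponsive"`. For `non_dv_visual` the transient
#'   has amplitude `beta0` independent of value; for `"unresponsive"` only
#'   baseline is generated.
#' @param seed integer seed.
#' @return a `neuron_gen_params` list.
#' @export
neuron_gen_params <- function(baseline_rate = 1, beta0 = 5, betaV = 4,
                              kernel = c(onset = 100, rise = 50, duration = 600),
                              coding_class = c("positive_dv", "negative_dv",
                                               "non_dv_visual", "unresponsive"),
                              seed = 1L) {
  coding_class <- match.arg(coding_class)
  check_number(baseline_rate, "baseline_rate", lower = 0)
  structure(list(baseline_rate = baseline_rate, beta0 = beta0, betaV = betaV,
                 kernel = kernel, coding_class = coding_class,
                 seed = as.integer(seed)),
            class = "neuron_gen_params")
}

# Trapezoidal response kernel sampled at 1 ms resolution over [lo, hi) ms.
kernel_shape <- function(bins_ms, kernel) {
  on <- kernel[["onset"]]; rise <- kernel[["rise"]]; dur <- kernel[["duration"]]
  s <- numeric(length(bins_ms))
  tt <- bins_ms - on
  inside <- tt >= 0 & tt < dur
  s[inside] <- pmin(1, (tt[inside] + 1) / max(rise, 1))
  fall <- tt >= dur - rise & tt < dur   # symmetric fall-off
  s[fall] <- pmin(s[fall], (dur - tt[fall]) / max(rise, 1))
  s
}

#' Generate a spike train for one neuron over a session's correct trials
#'
#' Spikes are drawn as an inhomogeneous Poisson process at 1 ms resolution:
#' a constant baseline everywhere plus, for value-coding and visual
#' classes, a cue-locked trapezoidal transient whose amplitude is
#' `max(0, beta0 + betaV * DV(condition))` (value classes) or `beta0`
#' (visual class). Timestamps are in ms relative to cue onset. Only correct
#' trials carry events and are simulated, mirroring the analysis rule that
#' only correct trials enter neuronal analyses.
#'
#' @param trials session data frame from [generate_session()].
#' @param neuron a [neuron_gen_params()].
#' @param dv_params named list/vector with `k` used to compute the
#'   trial-by-trial discounted value regressor.
#' @param t_pre_ms ms of pre-cue baseline to simulate (>= 700 so the 500 ms
#'   background window is covered).
#' @param t_post_ms ms after reward delivery to simulate.
#' @return an object of class `spike_data`; see [spike_data()].
#' @export
generate_spike_train <- function(trials, neuron, dv_params = list(k = 0.2),
                                 t_pre_ms = 700, t_post_ms = 500) {
  stopifnot(inherits(neuron, "neuron_gen_params"))
  ok <- trials$outcome == "correct"
  tr <- trials[ok, , drop = FALSE]
  if (nrow(tr) == 0) stopf("no correct trials to simulate")
  dv <- discounted_value(tr$reward_size, tr$delay_mean_s, dv_params[["k"]])
  amp <- switch(neuron$coding_class,
    positive_dv = ,
    negative_dv = pmax(0, neuron$beta0 + neuron$betaV * dv),
    non_dv_visual = rep(max(0, neuron$beta0), nrow(tr)),
    unresponsive = rep(0, nrow(tr)))
  with_seed(neuron$seed, {
    spikes <- vector("list", nrow(tr))
    for (i in seq_len(nrow(tr))) {
      t_end <- ceiling(1000 * (tr$reward_s[i])) + t_post_ms
      bins <- seq.int(-t_pre_ms, t_end - 1L)       # 1 ms bins
      rate <- rep(neuron$baseline_rate, length(bins))
      if (amp[i] > 0) {
        rate <- rate + amp[i] * kernel_shape(bins, neuron$kernel)
      }
      p <- pmin(rate * 1e-3, 1)
      hit <- runif(length(bins)) < p
      spikes[[i]] <- bins[hit] + 0.5               # bin centres, ms
    }
    spike_data(
      neuron_id = paste0("n", neuron$seed),
      spikes = spikes,
      events = data.frame(trial_index = tr$trial_index,
                          go_ms = 1000 * tr$go_s,
                          release_ms = 1000 * tr$release_s,
                          reward_ms = 1000 * tr$reward_s),
      meta = cbind(tr[, c("session_id", "trial_index", "reward_size",
                          "delay_class", "delay_mean_s", "rcum")],
                   dv = dv),
      coding_class = neuron$coding_class)
  })
}

#' Generate a labelled synthetic neuron population
#'
#' Each neuron gets its own behavioral session (same task and behavioral
#' parameters, deterministic sub-seed) and a coding class drawn from
#' `class_mix`. The ground-truth class is stored on each `spike_data`
#' object; the default mix reflects the recorded population (about 2/3
#' cue-responsive, of which roughly a quarter code value, twice as many
#' positively as negatively).
#'
#' @param n_neurons number of neurons.
#' @param class_mix named proportions over the four coding classes (summing
#'   to 1).
#' @param task a [task_spec()].
#' @param seed parent seed for behavior and spikes.
#' @param behavior named list of overrides for [behavior_gen_params()].
#' @param neuron named list of overrides for [neuron_gen_params()]
#'   (`betaV` is negated automatically for `negative_dv` neurons and the
#'   intercept raised so the rectified rate keeps a working range).
#' @return list of `spike_data` objects with attribute-free ground truth in
#'   `$coding_class`.
#' @export
generate_population <- function(n_neurons,
                                class_mix = c(positive_dv = 0.12,
                                              negative_dv = 0.06,
                                              non_dv_visual = 0.49,
                                              unresponsive = 0.33),
                                task = task_spec("delayed"), seed = 1L,
                                behavior = list(), neuron = list()) {
  if (n_neurons == 0) return(list())
  stopifnot(abs(sum(class_mix) - 1) < 1e-8)
  classes <- with_seed(seed, {
    sample(names(class_mix), n_neurons, replace = TRUE, prob = class_mix)
  })
  lapply(seq_len(n_neurons), function(i) {
    b <- do.call(behavior_gen_params,
                 modifyList(list(seed = child_seed(seed, i)), behavior))
    tr <- generate_session(task, b, session_id = paste0("s", i))
    ngp <- modifyList(list(coding_class = classes[i],
                           seed = child_seed(seed, 100000 + i)), neuron)
    if (classes[i] == "negative_dv") {
      bv <- if (!is.null(neuron$betaV)) neuron$betaV else 4
      b0 <- if (!is.null(neuron$beta0)) neuron$beta0 else 5
      ngp$betaV <- -bv
      ngp$beta0 <- b0 + bv * max(task$conditions$reward_size)
    }
    sd_ <- generate_spike_train(tr, do.call(neuron_gen_params, ngp),
                                dv_params = list(k = b$k))
    sd_$neuron_id <- paste0("n", i)
    sd_
  })
}
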