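# Shared fixtures, built in code at test time.

DELAYED <- task_spec("delayed")

# A small, fast behavioral world with realistic error-rate ranges (~0.1-0.6).
quick_sessions <- function(n_sessions, seed = 1, ...) {
  generate_sessions(DELAYED, n_sessions, seed = seed, a = 4, lambda = 0, ...)
}

# Exact (noiseless) rate table straight from a model's own predictions.
exact_rates <- function(model, k = 0.2, a = 2, lambda = 1,
                        by_quartile = FALSE, satiation_form = "value") {
  g <- DELAYED$conditions[, c("reward_size", "delay_class", "delay_mean_s")]
  if (by_quartile) {
    g <- merge(g, data.frame(rcum_bin = c(0.125, 0.375, 0.625, 0.875)))
  }
  g$error_rate <- tdvmotive:::predict_error_rate(
    model, g, list(k = k, a = a, lambda = lambda),
    satiation_form = satiation_form)
  g$n_trials <- 100L
  g$n_errors <- NA_integer_
  g
}

# One synthetic session's worth of correct-trial metadata + a neuron.
quick_neuron <- function(coding_class = "positive_dv", seed = 5,
                        n_correct = 120, baseline_rate = 1, beta0 = 5,
                        betaV = 5, kernel = c(onset = 100, rise = 50,
                                              duration = 600)) {
  tr <- generate_session(DELAYED,
                         behavior_gen_params(a = 4, lambda = 0, seed = seed,
                                             n_correct = n_correct))
  n <- neuron_gen_params(baseline_rate = baseline_rate, beta0 = beta0,
                         betaV = betaV, kernel = kernel,
                         coding_class = coding_class,
                         seed = seed + 1000)
  generate_spike_train(tr, n, dv_params = list(k = 0.2))
}

# local tempdir cleaned up at the end of the calling test
withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("tdv")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}
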