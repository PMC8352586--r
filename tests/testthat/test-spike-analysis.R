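# Response detection, rate windows, regression classification, timecourses.

test_that("detector handles degenerate input and finds injected steps", {
  tr <- generate_session(DELAYED, behavior_gen_params(a = 4, seed = 3,
                                                      n_correct = 30))
  silent <- generate_spike_train(
    tr, neuron_gen_params(baseline_rate = 0, coding_class = "unresponsive",
                          seed = 1))
  w <- detect_response(silent, "cue")
  expect_false(w$is_responsive)
  expect_true(is.na(w$start_ms))
  expect_equal(w$duration_ms, 0)

  # rectangular 10 -> 30 sp/s step over [100, 500] ms
  onsets <- vapply(1:25, function(i) {
    nn <- neuron_gen_params(baseline_rate = 10, beta0 = 20, betaV = 0,
                            kernel = c(onset = 100, rise = 1, duration = 400),
                            coding_class = "non_dv_visual", seed = 300 + i)
    detect_response(generate_spike_train(tr, nn), "cue")$start_ms
  }, numeric(1))
  expect_true(all(!is.na(onsets)))
  expect_gte(mean(abs(onsets - 100) <= 100), 0.95)
})

test_that("per-window chi-square matches stats::chisq.test without correction", {
  p_ours <- tdvmotive:::chisq_2x2(12L, 3000L, 20L, 15000L)
  p_ref <- chisq.test(matrix(c(12, 3000 - 12, 20, 15000 - 20), 2,
                             byrow = TRUE), correct = FALSE)$p.value
  expect_equal(p_ours, p_ref, tolerance = 1e-12)
  # zero-margin table is defined as non-significant
  expect_equal(tdvmotive:::chisq_2x2(0L, 100L, 0L, 500L), 1)
})

test_that("detection is event-specific and release alignment works", {
  tr <- generate_session(DELAYED, behavior_gen_params(a = 4, seed = 5,
                                                      n_correct = 60))
  sd_ <- quick_neuron("positive_dv", seed = 41, n_correct = 120, betaV = 6,
                      beta0 = 8)
  cue <- detect_response(sd_, "cue")
  expect_true(cue$is_responsive)
  expect_lt(abs(cue$start_ms - 100), 110)
  # the same neuron has no reward-locked elevation
  rew <- detect_response(sd_, "reward")
  expect_false(isTRUE(rew$is_responsive) && rew$duration_ms > 200)
})

test_that("response_rate equals a brute-force recount", {
  sd_ <- quick_neuron("positive_dv", seed = 19, n_correct = 60)
  w <- list(event = "cue", start_ms = 80, end_ms = 280)
  r <- response_rate(sd_, w)
  brute <- vapply(sd_$spikes, function(s) sum(s >= 80 & s < 280) / 0.2,
                  numeric(1))
  expect_identical(r, brute)
  # arithmetic: 3 spikes in 200 ms -> 15 sp/s
  one <- spike_data("x", list(c(10, 50, 150), numeric(0)),
                    data.frame(trial_index = 0:1, go_ms = c(1000, 1000),
                               release_ms = c(1300, 1300),
                               reward_ms = c(1600, 1600)),
                    data.frame(reward_size = c(3, 1),
                               delay_class = "immediate",
                               delay_mean_s = 0.3))
  expect_equal(response_rate(one, list(event = "cue", start_ms = 0,
                                       end_ms = 200)), c(15, 0))
  expect_error(response_rate(one, list(event = "cue", start_ms = 100,
                                       end_ms = 100)), "zero-duration")
})

test_that("fit_dv_regression identities hold", {
  dv <- rep(c(0.4, 0.8, 1.5, 2.1, 2.6, 3), each = 20)
  y <- 2 + 3 * dv
  f <- suppressWarnings(fit_dv_regression(y, dv))  # exact fit: lm warns
  expect_equal(unname(f$coefficients), c(2, 3), tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-10)

  set.seed(1)
  y <- 2 + 3 * dv + rnorm(length(dv), 0, 2)
  f <- fit_dv_regression(y, dv)
  expect_equal(f$r_squared, cor(y, dv)^2, tolerance = 1e-12)
  expect_equal(sign(f$sprc[["dv"]]), sign(f$coefficients[["dv"]]))
  expect_error(fit_dv_regression(y, rep(1, length(y))), "constant")
})

test_that("permuted DV labels are significant at ~alpha", {
  set.seed(42)
  dv <- rep(c(0.4, 0.8, 1.5, 2.1, 2.6, 3), each = 25)
  y <- rnorm(length(dv), 5, 2)
  hits <- vapply(1:1000, function(i) {
    fit_dv_regression(y, sample(dv))$p_values[["dv"]] < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.03); expect_lt(mean(hits), 0.07)
})

test_that("classify_neuron categories and affine invariance", {
  set.seed(7)
  meta <- DELAYED$conditions[rep(1:6, each = 25), ]
  dv <- discounted_value(meta$reward_size, meta$delay_mean_s, 0.2)
  # strong DV coder
  y <- 3 + 4 * dv + rnorm(nrow(meta), 0, 1.5)
  cl <- classify_neuron(y, meta$delay_mean_s, meta$reward_size, dv)
  expect_equal(cl$category, "DV")
  expect_gt(cl$sprc[["dv"]], 0)
  # affine rescaling leaves the category and SPRC signs unchanged
  cl2 <- classify_neuron(5 * y + 20, meta$delay_mean_s, meta$reward_size, dv)
  expect_equal(cl2$category, cl$category)
  expect_equal(sign(cl2$sprc), sign(cl$sprc))
  expect_equal(cl2$p_values, cl$p_values, tolerance = 1e-9)

  # pure size coder
  y <- 2 + 2 * meta$reward_size + rnorm(nrow(meta), 0, 1)
  expect_equal(classify_neuron(y, meta$delay_mean_s, meta$reward_size,
                               dv)$category, "Size")
  # collinear design refuses
  expect_warning(
    cl3 <- classify_neuron(y, meta$delay_mean_s, meta$reward_size,
                           2 * meta$reward_size),
    "collinear")
  expect_true(is.na(cl3$category))
})

test_that("baseline-only neurons usually classify NA under the 3-test family", {
  set.seed(11)
  meta <- DELAYED$conditions[rep(1:6, each = 25), ]
  dv <- discounted_value(meta$reward_size, meta$delay_mean_s, 0.2)
  cats <- vapply(1:200, function(i) {
    y <- rnorm(nrow(meta), 3, 1)
    classify_neuron(y, meta$delay_mean_s, meta$reward_size, dv)$category
  }, character(1))
  expect_gte(mean(cats == "NA"), 0.85)
})

test_that("dv_effect_timecourse tracks the response kernel", {
  sd_ <- quick_neuron("positive_dv", seed = 23, n_correct = 150, betaV = 6,
                      beta0 = 8, kernel = c(onset = 100, rise = 50,
                                            duration = 800))
  tc <- dv_effect_timecourse(sd_, "cue")
  expect_true(all(tc$r2 >= 0 & tc$r2 <= 1))
  pre <- tc$r2[tc$time_ms < 0]
  inside <- tc$r2[tc$time_ms > 150 & tc$time_ms < 900]
  expect_lt(mean(pre), 0.05)
  expect_gt(max(inside), 0.2)
  expect_true(tc$time_ms[which.max(tc$r2)] > 100)
  expect_true(tc$time_ms[which.max(tc$r2)] < 950)

  # negative control: time-reversed spikes show no pre-event structure
  rev_sd <- sd_
  rev_sd$spikes <- lapply(sd_$spikes, function(s) sort(-s))
  tc_rev <- dv_effect_timecourse(rev_sd, "cue", range = c(-1500, 0))
  expect_lt(mean(tc_rev$r2[tc_rev$time_ms < -950]), 0.05)
})

test_that("non-DV visual population timecourse stays at the permutation floor", {
  sd_ <- quick_neuron("non_dv_visual", seed = 29, n_correct = 150, beta0 = 10)
  tc <- dv_effect_timecourse(sd_, "cue", range = c(0, 1000))
  # permutation null band for the peak R2 over the same windows
  set.seed(1)
  null_peak <- vapply(1:40, function(i) {
    shuffled <- sd_
    shuffled$meta$dv <- sample(sd_$meta$dv)
    max(dv_effect_timecourse(shuffled, "cue", range = c(0, 1000))$r2)
  }, numeric(1))
  expect_lte(max(tc$r2), quantile(null_peak, 0.99) + 0.02)
})

test_that("satiation_regression nulls, effects, and orthogonality identity", {
  set.seed(3)
  meta <- DELAYED$conditions[rep(1:6, each = 25), ]
  dv <- discounted_value(meta$reward_size, meta$delay_mean_s, 0.2)
  # rcum constructed orthogonal to dv: coefficient on dv must match the
  # simple regression slope to numerical precision
  rc_raw <- runif(nrow(meta))
  cdv <- dv - mean(dv)
  rc <- rc_raw - cdv * sum(rc_raw * cdv) / sum(cdv^2)
  y <- 1 + 2 * dv + rnorm(nrow(meta), 0, 1)
  f9 <- satiation_regression(y, dv, rc)
  f7 <- fit_dv_regression(y, dv)
  expect_equal(f9$coefficients[["dv"]], f7$coefficients[["dv"]],
               tolerance = 1e-6)

  # rate independent of rcum: beta_rcum rarely significant
  sig <- vapply(1:100, function(i) {
    yy <- 1 + 2 * dv + rnorm(nrow(meta), 0, 1)
    satiation_regression(yy, dv, runif(nrow(meta)))$p_values[["rcum"]] < 0.05
  }, logical(1))
  expect_gte(mean(!sig), 0.9)

  # injected satiation drift is found, positive
  rc2 <- seq(0, 1, length.out = nrow(meta))
  y2 <- 1 + 2 * dv + 4 * rc2 + rnorm(nrow(meta), 0, 1)
  f <- satiation_regression(y2, dv, rc2)
  expect_lt(f$p_values[["rcum"]], 0.01)
  expect_gt(f$coefficients[["rcum"]], 0)
  expect_error(satiation_regression(y2, dv, rep(0.5, nrow(meta))), "range")
})

test_that("half_split_comparison normalizes by first-half immediate-large", {
  set.seed(5)
  meta <- DELAYED$conditions[rep(rep(1:6, each = 2), 10), ]
  meta <- meta[sample(nrow(meta)), ]
  rates <- rnorm(nrow(meta), 10, 1)
  hs <- half_split_comparison(rates, meta)
  expect_equal(dim(hs$matrix), c(6, 2))
  expect_equal(hs$matrix[1, "first"], 1)          # self-normalization
  expect_true(all(abs(hs$matrix - 1) < 0.5))      # stationary ~ 1

  # rate halved in the second half by construction
  n <- nrow(meta)
  rates2 <- c(rep(10, ceiling(n / 2)), rep(5, floor(n / 2)))
  hs2 <- half_split_comparison(rates2, meta)
  expect_equal(unname(hs2$matrix[, "second"] / hs2$matrix[, "first"]),
               rep(0.5, 6), tolerance = 1e-9)
})
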