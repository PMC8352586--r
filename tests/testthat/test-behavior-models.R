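# Discounting/satiation model primitives and their frozen example values.

test_that("discounted_value matches closed form and boundary cases", {
  expect_identical(discounted_value(3, 0, 0.2), 3)
  expect_identical(discounted_value(1, 6.9, 0), 1)
  expect_equal(discounted_value(3, 3.3, 0.15), 3 / 1.495, tolerance = 1e-12)
  # strictly decreasing in delay for k > 0
  d <- seq(0, 10, by = 0.25)
  expect_true(all(diff(discounted_value(2, d, 0.3)) < 0))
  expect_error(discounted_value(0, 1, 0.1), "positive")
  expect_error(discounted_value(1, -1, 0.1), "delay")
})

test_that("error_rate_hyperbolic is affine in delay and clips", {
  expect_equal(error_rate_hyperbolic(1, 0, 0.7, 2), 0.5)
  expect_equal(error_rate_hyperbolic(4, 0, 0.3, 1), 0.25)
  expect_equal(error_rate_hyperbolic(1, 10, 0.5, 2), 1)   # raw 3.0 clipped
  # affine in D where unclipped: second differences vanish
  d <- c(0, 1, 2, 3)
  e <- error_rate_hyperbolic(4, d, 0.1, 1)
  expect_equal(diff(diff(e)), c(0, 0), tolerance = 1e-14)
  expect_error(error_rate_hyperbolic(1, 0, 0.1, 0), "`a`")
})

test_that("error_rate_exponential supports both orientations", {
  expect_equal(error_rate_exponential(1, 0, 0.2, 2), 0.5)
  expect_equal(error_rate_exponential(3, 5, 0, 1.5),
               error_rate_hyperbolic(3, 0, 0, 1.5))
  expect_equal(error_rate_exponential(1, 3.3, 0.2, 2), exp(-0.66) / 2,
               tolerance = 1e-12)
  # value orientation rises with delay; printed falls
  d <- c(0, 2, 4)
  expect_true(all(diff(error_rate_exponential(3, d, 0.2, 1, "value")) > 0))
  expect_true(all(diff(error_rate_exponential(3, d, 0.2, 1, "printed")) < 0))
})

test_that("satiation factor and satiation-extended models", {
  expect_identical(satiation_factor(0, 5), 1)
  expect_identical(satiation_factor(1, 0), 1)
  expect_equal(satiation_factor(0.5, 1), exp(-0.5), tolerance = 1e-12)
  expect_error(satiation_factor(1.2, 1), "rcum")

  # lambda = 0 reduces bit-for-bit to the hyperbolic model, both forms
  g <- expand.grid(R = c(1, 3), D = c(0.3, 3.3, 6.9), rc = c(0, 0.5, 1))
  for (form in c("printed", "value")) {
    expect_identical(
      error_rate_with_satiation(g$R, g$D, g$rc, 0.2, 2, 0, form = form),
      error_rate_hyperbolic(g$R, g$D, 0.2, 2))
  }
  expect_equal(error_rate_with_satiation(1, 0, 1, 0, 2, 1, form = "printed"),
               0.5 * exp(-1), tolerance = 1e-12)
  # printed form monotone nonincreasing in rcum on a grid; value form rises
  rc <- seq(0, 1, by = 0.05)
  for (R in c(1, 3)) for (D in c(0.3, 6.9)) {
    expect_true(all(diff(error_rate_with_satiation(R, D, rc, 0.1, 4, 1.5,
                                                   form = "printed")) <= 0))
    expect_true(all(diff(error_rate_with_satiation(R, D, rc, 0.1, 4, 1.5,
                                                   form = "value")) >= 0))
  }
})

test_that("error_rate_reward_size follows the inverse-size model", {
  expect_equal(error_rate_reward_size(8, 0, 1, 0), 0.125)
  expect_equal(error_rate_reward_size(1, 0.7, 1, 0), 1)   # clip boundary
  expect_equal(error_rate_reward_size(2, 1, 1, 1), 1)     # e/2 clipped
  expect_equal(error_rate_reward_size(4, 0.5, 1, 1), exp(0.5) / 4,
               tolerance = 1e-12)
  rc <- seq(0, 1, 0.1)
  expect_true(all(diff(error_rate_reward_size(8, rc, 1, 2)) >= 0))
})

test_that("compute_error_rates counts and conserves", {
  tr <- data.frame(
    session_id = "s1", trial_index = 0:9, reward_size = 1,
    delay_class = "immediate", delay_mean_s = 0.3,
    outcome = c(rep("early", 3), "late", rep("correct", 6)))
  r <- compute_error_rates(tr)
  expect_equal(r$error_rate, 0.4)
  expect_equal(r$n_trials, 10L)

  tr$outcome <- "correct"
  expect_equal(compute_error_rates(tr)$error_rate, 0)

  s <- quick_sessions(3, seed = 42)
  r <- compute_error_rates(s)
  expect_equal(sum(r$n_trials), nrow(s))
  expect_equal(sum(r$n_errors), sum(s$outcome != "correct"))
  rq <- compute_error_rates(s, by_quartile = TRUE)
  expect_equal(sum(rq$n_trials), nrow(s))
  expect_setequal(unique(rq$rcum_bin), c(0.125, 0.375, 0.625, 0.875))

  tr$outcome[3] <- "oops"
  expect_error(compute_error_rates(tr), "row 3")
})

test_that("observed per-condition rates sit inside binomial 99% CI", {
  # generated at known p with lambda = 0 each trial is Bernoulli(p_cond)
  s <- quick_sessions(20, seed = 7)
  r <- compute_error_rates(s)
  p <- error_rate_hyperbolic(r$reward_size, r$delay_mean_s, 0.2, 4)
  z <- qnorm(0.995)
  se <- sqrt(p * (1 - p) / r$n_trials)
  expect_true(all(abs(r$error_rate - p) <= z * se + 1e-9))
})

test_that("fit recovers exact hyperbolic parameters and agrees with grid oracle", {
  r <- exact_rates("hyperbolic", k = 0.2, a = 2)
  fit <- fit_discount_model(r, "hyperbolic")
  expect_equal(unname(fit$params["k"]), 0.2, tolerance = 1e-4)
  expect_equal(unname(fit$params["a"]), 2, tolerance = 1e-4)
  expect_gte(fit$r_squared, 0.9999)
  # SSR equals an independent recount
  expect_equal(fit$ssr, sum((r$error_rate - fit$fitted)^2), tolerance = 1e-12)

  # independent oracle: dense grid search over (k, a)
  s <- quick_sessions(5, seed = 9)
  robs <- compute_error_rates(s)
  fit2 <- fit_discount_model(robs, "hyperbolic")
  grid <- expand.grid(k = seq(0.01, 1, by = 0.005), a = seq(1, 8, by = 0.005))
  ssr <- mapply(function(k, a) {
    sum((robs$error_rate -
           error_rate_hyperbolic(robs$reward_size, robs$delay_mean_s, k, a))^2)
  }, grid$k, grid$a)
  best <- grid[which.min(ssr), ]
  expect_equal(unname(fit2$params["k"]), best$k, tolerance = 0.01)
  expect_equal(unname(fit2$params["a"]), best$a, tolerance = 0.01)
  expect_lte(fit2$ssr, min(ssr) + 1e-10)
})

test_that("fit recovers exact satiation-model parameters", {
  r <- exact_rates("hyperbolic_satiation", k = 0.15, a = 1.5, lambda = 1,
                   by_quartile = TRUE)
  fit <- fit_discount_model(r, "hyperbolic_satiation")
  expect_equal(unname(fit$params[c("k", "a", "lambda")]), c(0.15, 1.5, 1),
               tolerance = 1e-3)
  expect_gte(fit$r_squared, 0.9999)
})

test_that("constant rates give k ~ 0 and near-zero r_squared", {
  r <- DELAYED$conditions
  r$error_rate <- 0.3
  r$n_trials <- 50L
  fit <- fit_discount_model(r, "hyperbolic")
  expect_lt(unname(fit$params["k"]), 1e-3)
  expect_lt(abs(fit$r_squared), 0.05)
})

test_that("empty groups are dropped with a warning", {
  r <- exact_rates("hyperbolic")
  r$n_trials[2] <- 0L
  expect_warning(fit <- fit_discount_model(r, "hyperbolic"), "empty")
  expect_equal(fit$n_points, 5L)
})

test_that("loo_cv_compare prefers the generating model and keeps errors >= 0", {
  s <- quick_sessions(8, seed = 21)
  by_sess <- lapply(split(s, s$session_id), compute_error_rates)
  cmp <- loo_cv_compare(by_sess, c("hyperbolic", "exponential"),
                        exp_orientation = "value")
  expect_true(all(cmp$per_fold_errors >= 0))
  expect_equal(cmp$preferred_model,
               names(which.min(colMeans(cmp$per_fold_errors))))
  expect_error(loo_cv_compare(by_sess[1:2]), ">= 3 sessions")
})

test_that("arcsine transform is the textbook map", {
  expect_equal(arcsine_transform(c(0, 0.5, 1)),
               c(0, asin(sqrt(0.5)), pi / 2), tolerance = 1e-12)
})
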