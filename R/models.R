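# Discounting and satiation error-rate models.
#
# The behavioral observable is the per-condition error rate E (proportion of
# trials released too early or too late), an inverse index of motivation.
# Motivation follows the temporally discounted value DV = R / (1 + kD) of the
# cued reward (R drops after D seconds), optionally devalued by satiation
# F(Rcum) = exp(-lambda * Rcum) as normalized cumulative reward accrues.

#' Temporally discounted value of a delayed reward
#'
#' Hyperbolic discounting: `DV = R / (1 + k * D)`, the drops-equivalent value
#' of `reward` drops delivered after `delay` seconds.
#'
#' @param reward reward magnitude in drops (> 0); vectorized.
#' @param delay delay to reward in seconds (>= 0); vectorized.
#' @param k discount rate in 1/seconds (>= 0).
#' @return numeric vector of discounted values.
#' @examples
#' discounted_value(3, c(0.3, 3.3, 6.9), k = 0.2)
#' @export
discounted_value <- function(reward, delay, k) {
  if (any(reward <= 0)) stopf("`reward` must be positive")
  check_number(delay, "delay", lower = 0)
  check_number(k, "k", lower = 0)
  reward / (1 + k * delay)
}

#' Predicted error rate under hyperbolic discounting
#'
#' `E = (1 + k * D) / (a * R)`, clipped to `[0, 1]`: the inverse of the
#' discounted value scaled by a subject-specific incentive parameter `a`.
#' Predictions are affine in delay at fixed reward size.
#'
#' @inheritParams discounted_value
#' @param a incentive scaling parameter in 1/drops (> 0).
#' @return predicted error proportion in `[0, 1]`.
#' @export
error_rate_hyperbolic <- function(reward, delay, k, a) {
  if (any(a <= 0)) stopf("`a` must be positive")
  if (any(reward <= 0)) stopf("`reward` must be positive")
  check_number(delay, "delay", lower = 0)
  clip01((1 + k * delay) / (a * reward))
}

#' Predicted error rate under exponential discounting
#'
#' The printed model is `E = exp(-k * D) / (a * R)`, which *decreases* with
#' delay for k > 0. Because the empirical error pattern rises with delay, the
#' value-placed orientation `E = 1 / (a * R * exp(-k * D))` is offered as
#' well; both are clipped to `[0, 1]`. Which orientation the original
#' analysis used is ambiguous, so neither is silently substituted for the
#' other (see the methods vignette).
#'
#' @inheritParams error_rate_hyperbolic
#' @param orientation `"printed"` for `exp(-kD)/(aR)`, `"value"` for
#'   `exp(kD)/(aR)` (errors rise as the exponentially discounted value falls).
#' @return predicted error proportion in `[0, 1]`.
#' @export
error_rate_exponential <- function(reward, delay, k, a,
                                   orientation = c("printed", "value")) {
  orientation <- match.arg(orientation)
  if (any(a <= 0)) stopf("`a` must be positive")
  if (any(reward <= 0)) stopf("`reward` must be positive")
  check_number(delay, "delay", lower = 0)
  disc <- if (orientation == "printed") exp(-k * delay) else exp(k * delay)
  clip01(disc / (a * reward))
}

#' Exponential satiation factor
#'
#' `F(Rcum) = exp(-lambda * Rcum)`: the multiplicative devaluation of reward
#' as the session-normalized cumulative reward `rcum` grows from 0 to 1.
#'
#' @param rcum normalized cumulative reward in `[0, 1]`.
#' @param lambda satiation decay constant (>= 0, per unit normalized reward).
#' @return multiplier in `(0, 1]`.
#' @export
satiation_factor <- function(rcum, lambda) {
  check_number(rcum, "rcum", 0, 1)
  check_number(lambda, "lambda", lower = 0)
  exp(-lambda * rcum)
}

#' Predicted error rate with hyperbolic discounting and satiation
#'
#' Extends [error_rate_hyperbolic()] with the satiation factor
#' [satiation_factor()]. Two placements are provided:
#' * `form = "printed"`: `E = (1 + kD) / (aR) * F(Rcum)` — the factor
#'   multiplies the error rate, so satiation *lowers* predicted errors;
#' * `form = "value"`: `E = (1 + kD) / (a * R * F(Rcum))` — the factor
#'   devalues the reward, so errors *rise* with satiation, matching the
#'   observed behavior. Simulation and satiation fitting default to this
#'   placement (see the methods vignette).
#'
#' At `lambda = 0` both forms reduce exactly to [error_rate_hyperbolic()].
#'
#' @inheritParams error_rate_hyperbolic
#' @inheritParams satiation_factor
#' @param form satiation placement, `"printed"` or `"value"`.
#' @return predicted error proportion in `[0, 1]`.
#' @export
error_rate_with_satiation <- function(reward, delay, rcum, k, a, lambda,
                                      form = c("printed", "value")) {
  form <- match.arg(form)
  f <- satiation_factor(rcum, lambda)
  base <- (1 + k * delay) / (a * reward)
  if (any(a <= 0)) stopf("`a` must be positive")
  if (form == "printed") clip01(base * f) else clip01(base / f)
}

#' Predicted error rate in the reward-size task
#'
#' Inverse reward-size model with satiation in the value:
#' `E = 1 / (a * R * F(Rcum))`, clipped to `[0, 1]`. Used for the task
#' variant in which all rewards are immediate and only size varies.
#'
#' @inheritParams error_rate_with_satiation
#' @return predicted error proportion in `[0, 1]`.
#' @export
error_rate_reward_size <- function(reward, rcum, a, lambda) {
  if (any(a <= 0)) stopf("`a` must be positive")
  if (any(reward <= 0)) stopf("`reward` must be positive")
  f <- satiation_factor(rcum, lambda)
  clip01(1 / (a * reward * f))
}

# Unified prediction over a rate table (reward_size, delay_mean_s, optional
# rcum_bin). `params` is a named vector/list with k, a, lambda as needed.
predict_error_rate <- function(model, data, params,
                               exp_orientation = "printed",
                               satiation_form = "value") {
  k <- if (!is.null(params[["k"]])) params[["k"]] else 0
  a <- params[["a"]]
  lambda <- if (!is.null(params[["lambda"]])) params[["lambda"]] else 0
  rcum <- if ("rcum_bin" %in% names(data)) data$rcum_bin else rep(0, nrow(data))
  switch(model,
    hyperbolic = error_rate_hyperbolic(data$reward_size, data$delay_mean_s, k, a),
    exponential = error_rate_exponential(data$reward_size, data$delay_mean_s,
                                         k, a, orientation = exp_orientation),
    hyperbolic_satiation = error_rate_with_satiation(
      data$reward_size, data$delay_mean_s, rcum, k, a, lambda,
      form = satiation_form),
    inverse_size_satiation = error_rate_reward_size(
      data$reward_size, rcum, a, lambda),
    stopf("unknown model '%s'", model)
  )
}

model_param_names <- function(model) {
  switch(model,
    hyperbolic = c("k", "a"),
    exponential = c("k", "a"),
    hyperbolic_satiation = c("k", "a", "lambda"),
    inverse_size_satiation = c("a", "lambda"),
    stopf("unknown model '%s'", model)
  )
}
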