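# Regression quantification of discounted-value coding.

sprc_from_lm <- function(fit, y) {
  b <- coef(fit)[-1]
  xs <- vapply(names(b), function(nm) sd(fit$model[[nm]]), numeric(1))
  b * xs / sd(y)
}

regression_fit <- function(fit, y, label) {
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(label = label,
                 coefficients = coef(fit),
                 sprc = sprc_from_lm(fit, y),
                 p_values = co[, "Pr(>|t|)"],
                 r_squared = sm$r.squared,
                 n = length(y)),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("%s regression (n = %d, R^2 = %.3f)\n", x$label, x$n, x$r_squared))
  tab <- data.frame(beta = x$coefficients,
                    sprc = c(NA, x$sprc)[seq_along(x$coefficients)],
                    p = x$p_values)
  print(round(tab, 4))
  invisible(x)
}

#' Simple linear regression of firing rate on discounted value
#'
#' Ordinary least squares `Y = b0 + bV * DV` with a two-sided t-test on the
#' slope. With a single regressor the coefficient of determination equals
#' the squared Pearson correlation between rate and value.
#'
#' @param rates per-trial firing rates (spikes/s).
#' @param dv per-trial discounted values (at least two distinct values).
#' @return a `regression_fit` with coefficients `(Intercept)`, `dv`.
#' @export
fit_dv_regression <- function(rates, dv) {
  if (length(unique(dv)) < 2) stopf("`dv` is constant; slope undefined")
  fit <- lm(rates ~ dv)
  regression_fit(fit, rates, "rate ~ DV")
}

#' Classify a neuron's cue response by multiple regression
#'
#' Fits `Y = b0 + b_delay * D + b_size * R + b_DV * DV` and assigns a
#' category from per-coefficient two-sided t-tests at `alpha` (no
#' multiplicity correction): `"DV"` when the value coefficient is
#' significant (whatever the others do), `"Size_and_Delay"` when both size
#' and delay are significant but value is not, `"Size"`/`"Delay"` when
#' exactly one of them is, `"NA"` otherwise. Standardized partial
#' regression coefficients (SPRC, `b * sd(x)/sd(Y)`) are returned as the
#' classification scatter coordinates.
#'
#' @param rates per-trial firing rates.
#' @param delay,size,dv per-trial regressors.
#' @param alpha per-coefficient significance level.
#' @return a `neuron_class` object: `category`, `sprc`, `p_values`,
#'   `fit` (the underlying `regression_fit`).
#' @export
classify_neuron <- function(rates, delay, size, dv, alpha = 0.05) {
  X <- cbind(1, delay, size, dv)
  if (qr(X)$rank < 4 || kappa(scale(X[, -1])) > 1e6) {
    warning("regressors are (near-)collinear; refusing to classify")
    return(structure(list(category = NA_character_, sprc = NULL,
                          p_values = NULL, fit = NULL),
                     class = "neuron_class"))
  }
  f <- lm(rates ~ delay + size + dv)
  rf <- regression_fit(f, rates, "rate ~ delay + size + DV")
  p <- rf$p_values[c("delay", "size", "dv")]
  sig <- p < alpha
  category <- if (sig[["dv"]]) "DV"
  else if (sig[["size"]] && sig[["delay"]]) "Size_and_Delay"
  else if (sig[["size"]]) "Size"
  else if (sig[["delay"]]) "Delay"
  else "NA"
  structure(list(category = category, sprc = rf$sprc, p_values = p, fit = rf),
            class = "neuron_class")
}

#' @export
print.neuron_class <- function(x, ...) {
  cat("category:", x$category, "\n")
  if (!is.null(x$sprc)) {
    cat("  SPRC:", paste(sprintf("%s = %.3f", names(x$sprc), x$sprc),
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Time-resolved effect size of discounted value
#'
#' Slides a `window_ms` window in `step_ms` increments over the alignment
#' range, computes per-trial spike counts per window, and records the
#' coefficient of determination of the rate-on-DV regression at each step
#' (0 when the counts do not vary).
#'
#' @param sd a [spike_data()]; its `meta$dv` column is the regressor unless
#'   `dv` is given.
#' @param alignment `"cue"` or `"release"`.
#' @param dv optional per-trial discounted values.
#' @param window_ms,step_ms window span and increment, ms.
#' @param range ms range relative to the alignment event; defaults to
#'   `c(-500, 1500)` for cue and `c(-1000, 500)` for release.
#' @return an `effect_size_timecourse`: `alignment`, `time_ms` (window
#'   centres), `r2`.
#' @export
dv_effect_timecourse <- function(sd, alignment = c("cue", "release"),
                                 dv = NULL, window_ms = 200, step_ms = 10,
                                 range = NULL) {
  alignment <- match.arg(alignment)
  if (is.null(range)) {
    range <- if (alignment == "cue") c(-500, 1500) else c(-1000, 500)
  }
  al <- align_spikes(sd, alignment)
  if (is.null(dv)) dv <- al$meta$dv
  if (is.null(dv)) stopf("no `dv` regressor available")
  starts <- seq(range[1], range[2] - window_ms, by = step_ms)
  # cumulative spike counts per trial over the range at 1 ms resolution
  r2 <- vapply(starts, function(s0) {
    y <- window_counts(al$spikes, s0, s0 + window_ms)
    if (stats::sd(y) < 1e-12) return(0)
    cor(y, dv)^2
  }, numeric(1))
  structure(list(alignment = alignment, time_ms = starts + window_ms / 2,
                 r2 = r2, window_ms = window_ms, step_ms = step_ms),
            class = "effect_size_timecourse")
}

#' Regression of firing rate on discounted value and satiation
#'
#' `Y = b0 + b_DV * DV + b_Rcum * Rcum`, with per-coefficient two-sided
#' t-tests; used to ask whether a cue response carries the physiological
#' satiation state over and above the discounted value.
#'
#' @param rates per-trial firing rates.
#' @param dv per-trial discounted values.
#' @param rcum per-trial normalized cumulative reward (must span a nonzero
#'   range).
#' @return a `regression_fit` with coefficients for `dv` and `rcum`.
#' @export
satiation_regression <- function(rates, dv, rcum) {
  if (diff(range(rcum)) < 1e-12) stopf("`rcum` spans no range")
  fit <- lm(rates ~ dv + rcum)
  regression_fit(fit, rates, "rate ~ DV + Rcum")
}

#' First- vs second-half comparison of cue responses
#'
#' Splits a neuron's correct trials at the midpoint of their order, averages
#' the response rate per condition in each half, and normalizes everything
#' by the first-half mean of the immediate-large condition (largest reward,
#' shortest delay). The resulting conditions x 2 matrix is intended for
#' external repeated-measures testing.
#'
#' @param rates per-trial rates aligned with `meta`.
#' @param meta data frame with `reward_size`, `delay_mean_s`, `delay_class`
#'   per trial, in session order.
#' @return list with `matrix` (normalized means, conditions x halves),
#'   `normalizer` (the condition label), and `gaps` (condition-half cells
#'   with fewer than 2 trials).
#' @export
half_split_comparison <- function(rates, meta) {
  n <- length(rates)
  stopifnot(nrow(meta) == n)
  half <- rep(c("first", "second"), c(ceiling(n / 2), floor(n / 2)))
  key <- paste(meta$reward_size, meta$delay_mean_s, sep = "x")
  conds <- unique(data.frame(key, reward_size = meta$reward_size,
                             delay_mean_s = meta$delay_mean_s))
  conds <- conds[order(-conds$reward_size, conds$delay_mean_s), ]
  m <- matrix(NA_real_, nrow(conds), 2,
              dimnames = list(conds$key, c("first", "second")))
  cnt <- m
  for (h in c("first", "second")) {
    for (i in seq_len(nrow(conds))) {
      idx <- half == h & key == conds$key[i]
      cnt[i, h] <- sum(idx)
      if (sum(idx) >= 1) m[i, h] <- mean(rates[idx])
    }
  }
  gaps <- which(cnt < 2, arr.ind = TRUE)
  if (nrow(gaps)) warning("condition/half cell(s) with < 2 trials flagged")
  norm <- m[1, "first"]   # immediate-large condition, first half
  if (!is.finite(norm) || norm == 0) stopf("normalizer response is empty or zero")
  list(matrix = m / norm, counts = cnt, normalizer = rownames(m)[1],
       gaps = gaps)
}
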