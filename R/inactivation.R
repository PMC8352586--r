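# Session normalization and the bootstrap SSR deviation test.
#
# To ask whether a treatment (muscimol or chemogenetic silencing) pushes the
# error-rate pattern away from what the discounting model can express, each
# session's per-condition rates are first divided by that session's maximum
# rate (removing between-session variance), a null distribution of best-fit
# SSRs is built by resampling baseline sessions, and the test condition's
# best-fit SSR is located in that distribution.

#' Normalize per-session error rates by the session maximum
#'
#' @param rates_by_session named list of per-session rate tables (as from
#'   [compute_error_rates()]); every session must contain all conditions.
#' @return named list of the same tables with `error_rate` divided by the
#'   session's maximum rate (column `norm_rate` added); sessions with no
#'   errors anywhere are dropped with a warning.
#' @export
normalize_sessions <- function(rates_by_session) {
  out <- lapply(rates_by_session, function(r) {
    m <- max(r$error_rate)
    if (m == 0) return(NULL)
    r$norm_rate <- r$error_rate / m
    r
  })
  drop <- vapply(out, is.null, logical(1))
  if (any(drop)) {
    warning(sum(drop), " session(s) with zero errors everywhere excluded")
  }
  out[!drop]
}

# Per-condition mean of normalized rates across sessions. Sessions must
# share the condition grid; rows are matched by (reward_size, delay_mean_s).
mean_normalized <- function(norm_sessions) {
  template <- norm_sessions[[1]][, c("reward_size", "delay_class", "delay_mean_s")]
  key <- function(r) paste(r$reward_size, r$delay_mean_s)
  k0 <- key(template)
  mat <- vapply(norm_sessions,
                function(r) r$norm_rate[match(k0, key(r))],
                numeric(nrow(template)))
  template$error_rate <- rowMeans(matrix(mat, nrow = nrow(template)))
  template
}

# Fast per-resample model fit returning only SSRs. The hyperbolic model has
# an analytic path (see hyperbolic_nnls); other models fall back to the
# full optimizer with a reduced restart count.
boot_fit_ssr <- function(Y, template, model, ...) {
  if (model == "hyperbolic") {
    hyperbolic_nnls(Y, template$reward_size, template$delay_mean_s)$ssr
  } else {
    apply(Y, 1, function(y) {
      d <- template
      d$error_rate <- y
      fit_discount_model(d, model, ..., n_starts = 5)$ssr
    })
  }
}

#' Bootstrap test for deviation from the discounting model
#'
#' Builds the null distribution of best-fit SSRs by drawing
#' `resample_size` sessions with replacement from the normalized baseline
#' pool, averaging their per-condition normalized rates, and refitting the
#' model to each average (`n_resamples` times). The observed statistic is
#' the model's best-fit SSR on `test_mean` (the mean normalized rates of
#' the control or inactivation sessions). The one-sided p-value uses the
#' add-one estimator `p = (1 + #\{SSR_null >= SSR_obs\}) / (1 + n)`.
#'
#' `method = "simulate"` offers the alternative reading of a parametric
#' bootstrap: session rate vectors are simulated from the baseline fit with
#' binomial trial noise instead of being resampled.
#'
#' @param baseline named list of baseline per-session rate tables (raw; they
#'   are normalized internally via [normalize_sessions()]).
#' @param test_mean per-condition mean normalized rates of the test
#'   condition: a data frame with `reward_size`, `delay_mean_s`,
#'   `error_rate`; or a list of test-session rate tables, which is
#'   normalized and averaged first.
#' @param model model fitted inside the bootstrap (`"hyperbolic"` for the
#'   delayed-reward task, `"inverse_size_satiation"` for the reward-size
#'   task).
#' @param n_resamples bootstrap resamples (the reference analysis used
#'   20,000).
#' @param resample_size sessions per resample (5 for delayed reward, 4 for
#'   reward-size).
#' @param seed integer seed.
#' @param method `"resample"` (resample sessions, the literal procedure) or
#'   `"simulate"` (simulate rates from the fitted model with binomial
#'   noise; needs `n_trials` columns in the baseline tables).
#' @param ... passed to the model fitter for non-hyperbolic models.
#' @return a `bootstrap_result`: `ssr_null`, `ssr_observed`, `p_value`,
#'   `n_resamples`, `resample_size`, `seed`.
#' @export
bootstrap_ssr_test <- function(baseline, test_mean, model = "hyperbolic",
                               n_resamples = 20000, resample_size = 5,
                               seed = 1L, method = c("resample", "simulate"),
                               ...) {
  method <- match.arg(method)
  norm <- normalize_sessions(baseline)
  if (length(norm) < resample_size) {
    stopf("baseline pool (%d sessions) smaller than resample_size (%d)",
          length(norm), resample_size)
  }
  template <- norm[[1]][, c("reward_size", "delay_class", "delay_mean_s")]
  key <- paste(template$reward_size, template$delay_mean_s)
  S <- vapply(norm, function(r) {
    r$norm_rate[match(key, paste(r$reward_size, r$delay_mean_s))]
  }, numeric(nrow(template)))          # conditions x sessions

  if (is.data.frame(test_mean)) {
    obs <- test_mean$error_rate[match(key, paste(test_mean$reward_size,
                                                 test_mean$delay_mean_s))]
  } else {
    obs <- mean_normalized(normalize_sessions(test_mean))$error_rate
  }
  if (anyNA(obs)) stopf("test_mean does not cover the baseline condition grid")

  Y <- with_seed(seed, {
    if (method == "resample") {
      idx <- matrix(sample.int(ncol(S), n_resamples * resample_size,
                               replace = TRUE), nrow = n_resamples)
      t(apply(idx, 1, function(i) rowMeans(S[, i, drop = FALSE])))
    } else {
      # simulate: binomial noise around the baseline-mean fit
      mtab <- template
      mtab$error_rate <- rowMeans(S)
      fit <- fit_discount_model(mtab, model, ...)
      ntr <- round(mean(vapply(norm, function(r) mean(r$n_trials), numeric(1))))
      p <- clip01(predict(fit, mtab))
      t(vapply(seq_len(n_resamples), function(i) {
        sim <- vapply(seq_len(resample_size), function(j) {
          r <- rbinom(length(p), ntr, p) / ntr
          if (max(r) > 0) r / max(r) else r
        }, numeric(length(p)))
        rowMeans(sim)
      }, numeric(nrow(template))))
    }
  })
  ssr_null <- boot_fit_ssr(Y, template, model, ...)
  ssr_obs <- boot_fit_ssr(matrix(obs, nrow = 1), template, model, ...)
  p <- (1 + sum(ssr_null >= ssr_obs)) / (1 + n_resamples)
  structure(list(ssr_null = ssr_null, ssr_observed = ssr_obs, p_value = p,
                 n_resamples = n_resamples, resample_size = resample_size,
                 model = model, method = method, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap SSR test (%s, %s, n = %d, resample size %d)\n",
              x$model, x$method, x$n_resamples, x$resample_size))
  cat(sprintf("  observed SSR = %.5g, null 95%% quantile = %.5g, p = %.4g\n",
              x$ssr_observed, quantile(x$ssr_null, 0.95), x$p_value))
  invisible(x)
}

#' Mean trial-initiation time, first vs second half of each session
#'
#' The trial initiation time is the interval between the previous trial's
#' reward and the lever grip starting the current trial; the first trial of
#' each session has none and is excluded. No test is performed; the split
#' is emitted for external ANOVA.
#'
#' @param trials trial table with `session_id`, `trial_index`, and
#'   `init_time_s` columns.
#' @return data frame with one row per session and half: `session_id`,
#'   `half`, `mean_init_s`, `n`.
#' @export
trial_initiation_split <- function(trials) {
  if (!"init_time_s" %in% names(trials)) stopf("no `init_time_s` column")
  out <- lapply(split(trials, trials$session_id), function(s) {
    s <- s[order(s$trial_index), ]
    keep <- is.finite(s$init_time_s)
    x <- s$init_time_s[keep]
    if (length(x) < 4) stopf("need >= 2 trials per half in session %s",
                             s$session_id[1])
    h <- rep(c("first", "second"), c(ceiling(length(x) / 2),
                                     floor(length(x) / 2)))
    data.frame(session_id = s$session_id[1], half = c("first", "second"),
               mean_init_s = c(mean(x[h == "first"]), mean(x[h == "second"])),
               n = c(sum(h == "first"), sum(h == "second")))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
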