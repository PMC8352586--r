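# Least-squares fitting of the discounting/satiation models and
# leave-one-out cross-validated model comparison.

DISCOUNT_MODELS <- c("hyperbolic", "exponential", "hyperbolic_satiation",
                     "inverse_size_satiation")

# Analytic fast path for the hyperbolic model. E = (1+kD)/(aR) is linear in
# c1 = 1/a and c2 = k/a with regressors 1/R and D/R, both coefficients
# nonnegative, so the least-squares fit reduces to a 2-parameter NNLS with a
# closed form (unconstrained solve, else the better of the two boundary
# fits). `Y` may be a matrix with one rate vector per row; returns per-row
# (c1, c2, ssr) where ssr is computed on `[0, 1]`-clipped predictions.
hyperbolic_nnls <- function(Y, reward, delay) {
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1)
  x1 <- 1 / reward
  x2 <- delay / reward
  s11 <- sum(x1 * x1); s12 <- sum(x1 * x2); s22 <- sum(x2 * x2)
  det <- s11 * s22 - s12 * s12
  b1 <- as.vector(Y %*% x1)
  b2 <- as.vector(Y %*% x2)
  if (det > 1e-12 * s11 * s22) {
    c1 <- (s22 * b1 - s12 * b2) / det
    c2 <- (s11 * b2 - s12 * b1) / det
  } else {                                 # degenerate design: single ray
    c1 <- pmax(0, b1) / s11
    c2 <- rep(0, nrow(Y))
  }
  neg <- c1 < 0 | c2 < 0
  if (any(neg)) {
    # candidate boundary solutions (one coefficient pinned at zero)
    c1a <- pmax(0, b1[neg]) / s11
    c2b <- pmax(0, b2[neg]) / s22
    ssr_a <- rowSums((Y[neg, , drop = FALSE] -
                        pmin(1, outer(c1a, x1)))^2)
    ssr_b <- rowSums((Y[neg, , drop = FALSE] -
                        pmin(1, outer(c2b, x2)))^2)
    use_a <- ssr_a <= ssr_b
    c1[neg] <- ifelse(use_a, c1a, 0)
    c2[neg] <- ifelse(use_a, 0, c2b)
  }
  pred <- pmin(1, outer(c1, x1) + outer(c2, x2))
  list(c1 = c1, c2 = c2, ssr = rowSums((Y - pred)^2))
}

# Log-uniform multistart draws over plausible parameter ranges.
start_ranges <- list(k = c(1e-4, 2), a = c(0.2, 50), lambda = c(0.01, 10))

#' Fit a discounting/satiation error-rate model by least squares
#'
#' Minimizes the sum of squared residuals between observed per-condition
#' error rates and model predictions (clipped to `[0, 1]`), using
#' multi-start Nelder-Mead minimization in log-parameter space (all
#' parameters are nonnegative by construction). For the hyperbolic model an
#' analytic nonnegative-least-squares solution seeds the optimizer.
#'
#' @param data rate table as returned by [compute_error_rates()]: columns
#'   `reward_size`, `delay_mean_s`, `error_rate`, optionally `rcum_bin` and
#'   `n_trials`. Groups with `n_trials == 0` are dropped with a warning.
#' @param model one of `"hyperbolic"`, `"exponential"`,
#'   `"hyperbolic_satiation"`, `"inverse_size_satiation"`.
#' @param exp_orientation orientation of the exponential model, see
#'   [error_rate_exponential()].
#' @param satiation_form satiation placement, see
#'   [error_rate_with_satiation()]; the fitting default is the value-placed
#'   form, under which errors rise with satiation.
#' @param n_starts number of random restarts (in addition to deterministic
#'   seeds).
#' @param seed integer seed for the restart draws; fixed default makes fits
#'   deterministic.
#' @return an object of class `discount_fit`: list with `model`, `params`
#'   (named `k`, `a`, `lambda` as applicable), `ssr`, `r_squared`,
#'   `n_points`, `fitted`, `data`, `convergence`.
#' @export
fit_discount_model <- function(data, model = DISCOUNT_MODELS,
                               exp_orientation = c("printed", "value"),
                               satiation_form = c("value", "printed"),
                               n_starts = 20, seed = 1L) {
  model <- match.arg(model)
  exp_orientation <- match.arg(exp_orientation)
  satiation_form <- match.arg(satiation_form)
  if ("n_trials" %in% names(data) && any(data$n_trials == 0)) {
    warning("dropping ", sum(data$n_trials == 0), " empty group(s) from fit")
    data <- data[data$n_trials > 0, , drop = FALSE]
  }
  check_number(data$error_rate, "error_rate", 0, 1)
  pnames <- model_param_names(model)
  if (grepl("satiation", model) && !"rcum_bin" %in% names(data)) {
    pnames <- setdiff(pnames, "lambda")   # lambda unidentifiable without rcum
  }
  y <- data$error_rate
  n <- length(y)
  if (n < length(pnames)) stopf("%d points cannot constrain %d parameters",
                                n, length(pnames))

  obj <- function(theta) {
    p <- as.list(exp(theta))
    names(p) <- pnames
    pred <- predict_error_rate(model, data, p,
                               exp_orientation = exp_orientation,
                               satiation_form = satiation_form)
    sum((y - pred)^2)
  }

  starts <- with_seed(seed, {
    replicate(n_starts, vapply(pnames, function(nm) {
      r <- start_ranges[[nm]]
      exp(runif(1, log(r[1]), log(r[2])))
    }, numeric(1)), simplify = FALSE)
  })
  # deterministic seeds: mid-range point and, for hyperbolic-family models,
  # the analytic NNLS solution
  mid <- vapply(pnames, function(nm) sqrt(prod(start_ranges[[nm]])), numeric(1))
  starts <- c(list(mid), starts)
  if (model %in% c("hyperbolic", "hyperbolic_satiation")) {
    nn <- hyperbolic_nnls(y, data$reward_size, data$delay_mean_s)
    if (nn$c1 > 1e-12) {
      s <- c(k = max(nn$c2 / nn$c1, 1e-8), a = 1 / nn$c1)
      if ("lambda" %in% pnames) s <- c(s, lambda = 1e-6)
      starts <- c(list(s[pnames]), starts)
    }
  }

  run_optim <- function(theta0, maxit) {
    if (length(pnames) == 1L) {
      optim(theta0, obj, method = "Brent", lower = log(1e-8), upper = log(1e8))
    } else {
      optim(theta0, obj, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = 1e-12))
    }
  }
  best <- NULL
  convs <- integer(0)
  for (s in starts) {
    theta0 <- log(pmax(unlist(s), 1e-10))
    fit <- tryCatch(run_optim(theta0, 1000), error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value)) next
    convs <- c(convs, fit$convergence)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop(structure(class = c("tdv_fit_failure", "error", "condition"),
                   list(message = sprintf("all %d restarts failed for model '%s'",
                                          length(starts), model),
                        call = sys.call(-1))))
  }
  # polish from the best optimum (Nelder-Mead restart sharpens the simplex)
  best <- if (length(pnames) == 1L) best else {
    optim(best$par, obj, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-14))
  }

  params <- setNames(exp(best$par), pnames)
  full <- c(k = 0, a = NA_real_, lambda = 0)
  full[pnames] <- params
  pred <- predict_error_rate(model, data, as.list(params),
                             exp_orientation = exp_orientation,
                             satiation_form = satiation_form)
  ssr <- sum((y - pred)^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- if (sstot > 1e-14) 1 - ssr / sstot else 0
  structure(list(model = model, params = full[!is.na(full)],
                 free_params = pnames, ssr = ssr, r_squared = r2,
                 n_points = n, fitted = pred, data = data,
                 exp_orientation = exp_orientation,
                 satiation_form = satiation_form,
                 convergence = best$convergence, n_restarts_ok = length(convs)),
            class = "discount_fit")
}

#' @export
print.discount_fit <- function(x, ...) {
  cat("Discounting model fit:", x$model, "\n")
  cat("  parameters:",
      paste(sprintf("%s = %.4g", names(x$params), x$params), collapse = ", "),
      "\n")
  cat(sprintf("  SSR = %.5g, R^2 = %.4f over %d points\n",
              x$ssr, x$r_squared, x$n_points))
  invisible(x)
}

#' Predictions from a fitted discounting model
#'
#' @param object a `discount_fit`.
#' @param newdata optional rate-table-shaped data frame; defaults to the
#'   fitted data.
#' @param ... unused.
#' @return numeric vector of predicted (clipped) error rates.
#' @export
predict.discount_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  predict_error_rate(object$model, newdata, as.list(object$params),
                     exp_orientation = object$exp_orientation,
                     satiation_form = object$satiation_form)
}

#' Leave-one-session-out cross-validated model comparison
#'
#' For each held-out session, both models are fitted to the remaining
#' sessions' pooled rates (counts summed per condition) and scored by the
#' mean squared prediction error on the held-out session's per-condition
#' rates. The preferred model has the lower mean fold error; fold errors
#' are compared by a paired two-sided Wilcoxon signed-rank test.
#'
#' @param rates_by_session named list of per-session rate tables (each as
#'   from [compute_error_rates()], with `n_trials`/`n_errors` counts).
#' @param models character vector of two model names to compare.
#' @param ... passed to [fit_discount_model()] (e.g. `exp_orientation`).
#' @param n_starts restarts per fold fit (smaller than the default for speed;
#'   each fold also gets the deterministic analytic seed where applicable).
#' @return an object of class `model_comparison`: `per_fold_errors` (matrix
#'   folds x models), `mean_errors`, `preferred_model`, `p_value`.
#' @export
loo_cv_compare <- function(rates_by_session, models = c("hyperbolic", "exponential"),
                           ..., n_starts = 8) {
  if (length(rates_by_session) < 3) stopf("need >= 3 sessions for LOO-CV")
  if (length(models) != 2) stopf("`models` must name exactly two models")
  nfold <- length(rates_by_session)
  errs <- matrix(NA_real_, nfold, 2, dimnames = list(names(rates_by_session), models))
  for (i in seq_len(nfold)) {
    train <- pool_rates(rates_by_session[-i])
    test <- rates_by_session[[i]]
    for (j in 1:2) {
      fit <- fit_discount_model(train, models[j], ..., n_starts = n_starts)
      pred <- predict(fit, test)
      errs[i, j] <- mean((test$error_rate - pred)^2)
    }
  }
  mean_err <- colMeans(errs)
  pv <- tryCatch(
    wilcox.test(errs[, 1], errs[, 2], paired = TRUE, exact = FALSE)$p.value,
    error = function(e) NA_real_)
  structure(list(per_fold_errors = errs, mean_errors = mean_err,
                 preferred_model = models[which.min(mean_err)], p_value = pv),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Leave-one-session-out model comparison\n")
  print(round(x$mean_errors, 6))
  cat(sprintf("  preferred: %s (paired Wilcoxon p = %.4g)\n",
              x$preferred_model, x$p_value))
  invisible(x)
}
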