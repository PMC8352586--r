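# Aggregation of trial tables into per-condition (x quartile) error rates.

#' Per-condition error rates from a trial table
#'
#' Counts early + late outcomes per reward-size-and-delay condition
#' (optionally further split into quartiles of normalized cumulative reward)
#' and divides by the number of trials. Repeated post-error trials count as
#' ordinary trials. Quartile bins are labelled by their midpoints 0.125,
#' 0.375, 0.625, 0.875.
#'
#' @param trials data frame with columns `reward_size`, `delay_class`,
#'   `delay_mean_s`, `outcome` (one of `"correct"`, `"early"`, `"late"`),
#'   and, when `by_quartile = TRUE`, `rcum` in `[0, 1]`.
#' @param by_quartile split each condition into four bins of `rcum`?
#' @return data frame with columns `reward_size`, `delay_class`,
#'   `delay_mean_s`, (`rcum_bin`,) `n_trials`, `n_errors`, `error_rate`,
#'   one row per non-empty group.
#' @export
compute_error_rates <- function(trials, by_quartile = FALSE) {
  req <- c("reward_size", "delay_class", "delay_mean_s", "outcome")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stopf("`trials` lacks column(s): %s", paste(miss, collapse = ", "))
  bad <- !trials$outcome %in% c("correct", "early", "late")
  if (any(bad)) {
    stopf("unknown outcome '%s' at row %d", trials$outcome[which(bad)[1]],
          which(bad)[1])
  }
  keys <- trials[, c("reward_size", "delay_class", "delay_mean_s")]
  if (by_quartile) {
    if (!"rcum" %in% names(trials)) stopf("`by_quartile` needs an `rcum` column")
    check_number(trials$rcum, "rcum", 0, 1)
    q <- findInterval(trials$rcum, c(0.25, 0.5, 0.75)) + 1L
    keys$rcum_bin <- c(0.125, 0.375, 0.625, 0.875)[q]
  }
  is_err <- as.integer(trials$outcome != "correct")
  agg <- aggregate(cbind(n_trials = rep(1L, nrow(trials)), n_errors = is_err),
                   by = keys, FUN = sum)
  agg$error_rate <- agg$n_errors / agg$n_trials
  ord <- order(agg$reward_size, agg$delay_mean_s,
               if (by_quartile) agg$rcum_bin else rep(0, nrow(agg)))
  agg <- agg[ord, , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

# Pool per-session rate tables by summing counts within conditions.
pool_rates <- function(rate_list) {
  all <- do.call(rbind, rate_list)
  keycols <- intersect(c("reward_size", "delay_class", "delay_mean_s", "rcum_bin"),
                       names(all))
  agg <- aggregate(all[, c("n_trials", "n_errors")], by = all[keycols], FUN = sum)
  agg$error_rate <- agg$n_errors / agg$n_trials
  agg[order(agg$reward_size, agg$delay_mean_s), , drop = FALSE]
}
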