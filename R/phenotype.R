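#' Synchrony-stability score from an RWTLCC matrix
#'
#' Fraction of epochs whose peak-association lag lies within `tol_lags`
#' sampling steps of the modal peak lag. A score of 1 means the association
#' is stationary (a "vertical stripe" down the RWTLCC heat map); low scores
#' mean the lag wanders between epochs.
#'
#' @param rw matrix from [rwtlcc()] (epochs x lags, `lags` attribute).
#' @param tol_lags tolerance around the modal lag, in sampling steps.
#' @return Score in `[0, 1]`.
#' @export
synchrony_stability <- function(rw, tol_lags = 1) {
  if (!is.matrix(rw) || nrow(rw) < 1) hpa_stop("need at least one epoch row", "value_error")
  lags <- attr(rw, "lags") %||% seq_len(ncol(rw))
  arg <- apply(rw, 1, function(r) pick_peak_lag(lags, r))
  tab <- table(arg)
  modal <- as.integer(names(tab)[which.max(tab)])  # ties: first = smallest index
  mean(abs(arg - modal) <= tol_lags)
}

#' Classify a subject's dynamic phenotype
#'
#' Operationalises the grouping of post-surgical HPA-axis responses into
#' single-pulse, two-pulse and multiple-pulse phenotypes (plus a
#' control-like class for intact ultradian profiles) from the synchrony
#' metrics. Ordered decision rules:
#' \enumerate{
#'   \item pulse count `<= 1` -> `single_pulse`;
#'   \item pulse count 2, period `>= period_long`, stability
#'     `>= stability_min` -> `two_pulse`;
#'   \item pulse count `>= 3`, period `<= period_short`, |peak lag|
#'     `>= lag_high` -> `multiple_pulse`;
#'   \item pulse count `>= 3`, |peak lag| `<= lag_low`, stability
#'     `>= stability_min` -> `control_like`;
#'   \item otherwise the nearest rule under a normalised distance on
#'     (pulses, period, |lag|, stability).
#' }
#' All thresholds come from the [analysis_config()].
#'
#' @param metrics a [compute_sync_metrics()] result (or a list with fields
#'   `n_pulses`, `period`, `peak_lag`, `stability`).
#' @param config an [analysis_config()].
#' @return A list of class `phenotype_call` with `label`, `evidence` and
#'   `rule_trace`.
#' @export
classify_profile <- function(metrics, config = analysis_config()) {
  np <- metrics$n_pulses
  period <- metrics$period
  lag <- abs(metrics$peak_lag)
  stab <- metrics$stability
  evidence <- list(n_pulses = np, period_min = period, peak_lag_min = metrics$peak_lag,
                   stability_score = stab)
  # deficit of each rule's conditions, in comparable units
  # (1 pulse ~ 60 min of period ~ 20 min of lag ~ 0.2 of stability)
  pna <- 2  # penalty when a rule needs a period but none is defined
  d_period <- function(cmp, thr) {
    if (is.na(period)) pna else max(0, if (cmp == ">=") thr - period else period - thr) / 60
  }
  dist <- c(
    single_pulse  = max(0, np - 1),
    two_pulse     = abs(np - 2) + d_period(">=", config$period_long) +
                    max(0, config$stability_min - stab) / 0.2,
    multiple_pulse = max(0, 3 - np) + d_period("<=", config$period_short) +
                    max(0, config$lag_high - lag) / 20,
    control_like  = max(0, 3 - np) + max(0, lag - config$lag_low) / 20 +
                    max(0, config$stability_min - stab) / 0.2
  )
  trace <- character(0)
  label <- NULL
  if (np <= 1) {
    label <- "single_pulse"; trace <- "rule1: n_pulses <= 1"
  } else if (np == 2 && !is.na(period) && period >= config$period_long &&
             stab >= config$stability_min) {
    label <- "two_pulse"
    trace <- sprintf("rule2: n_pulses == 2, period %.0f >= %g, stability %.2f >= %g",
                     period, config$period_long, stab, config$stability_min)
  } else if (np >= 3 && !is.na(period) && period <= config$period_short &&
             lag >= config$lag_high) {
    label <- "multiple_pulse"
    trace <- sprintf("rule3: n_pulses >= 3, period %.0f <= %g, |lag| %.0f >= %g",
                     period, config$period_short, lag, config$lag_high)
  } else if (np >= 3 && lag <= config$lag_low && stab >= config$stability_min) {
    label <- "control_like"
    trace <- sprintf("rule4: n_pulses >= 3, |lag| %.0f <= %g, stability %.2f >= %g",
                     lag, config$lag_low, stab, config$stability_min)
  } else {
    label <- names(dist)[which.min(dist)]
    trace <- sprintf("rule5: nearest rule by distance (%s)",
                     paste(sprintf("%s=%.2f", names(dist), dist), collapse = ", "))
  }
  structure(list(label = label, evidence = evidence, rule_trace = trace),
            class = "phenotype_call")
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat(sprintf("<phenotype_call> %s (pulses %s, period %s min, lag %s min, stability %s)\n  %s\n",
              x$label, x$evidence$n_pulses,
              format(x$evidence$period_min), format(x$evidence$peak_lag_min),
              format(round(x$evidence$stability_score, 2)),
              paste(x$rule_trace, collapse = "; ")))
  invisible(x)
}
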