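#' Analysis configuration
#'
#' One bag of tunables shared by the synchrony battery, the phenotype
#' classifier and the model-calibration stages. Every threshold that
#' operationalises a qualitative boundary is exposed here.
#'
#' @param rolling_window rolling Pearson correlation window, minutes.
#' @param max_lag TLCC lag range, minutes (each side).
#' @param rwtlcc_window,rwtlcc_step,rwtlcc_max_lag rolling-window TLCC
#'   geometry, minutes. The window must hold at least `2*max_lag + 3` samples.
#' @param band ultradian band-pass edges for phase extraction, minutes
#'   (periods).
#' @param pulse_prominence minimum peak prominence as a fraction of the trace
#'   range.
#' @param pulse_separation minimum spacing between counted pulses, minutes.
#' @param period_long,period_short period thresholds (minutes) separating the
#'   long-period two-pulse regime and near-physiological periodicity.
#' @param lag_low,lag_high peak-lag thresholds (minutes): below `lag_low` is
#'   near-physiological association, above `lag_high` is strong dissociation.
#' @param stability_min minimum synchrony-stability score for "stable".
#' @param stability_tol_lags tolerance (in sampling steps) around the modal
#'   peak lag when scoring stability.
#' @param scenario calibration scenario: free adrenal sensitivity, fixed
#'   sensitivity, fixed Hill coefficient, or both fixed.
#' @param n_draws,keep random-search draws and number of kept best fits.
#' @param seed default seed for seeded stages.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(rolling_window = 60,
                            max_lag = 180,
                            rwtlcc_window = 240, rwtlcc_step = 30, rwtlcc_max_lag = 90,
                            band = c(60, 480),
                            pulse_prominence = 0.2, pulse_separation = 60,
                            period_long = 240, period_short = 210,
                            lag_low = 20, lag_high = 40,
                            stability_min = 0.7, stability_tol_lags = 1,
                            scenario = c("free_KA", "fixed_KA", "fixed_m", "fixed_both"),
                            n_draws = 1e5, keep = NULL, seed = 1L) {
  scenario <- match.arg(scenario)
  cfg <- list(rolling_window = rolling_window, max_lag = max_lag,
              rwtlcc_window = rwtlcc_window, rwtlcc_step = rwtlcc_step,
              rwtlcc_max_lag = rwtlcc_max_lag, band = band,
              pulse_prominence = pulse_prominence, pulse_separation = pulse_separation,
              period_long = period_long, period_short = period_short,
              lag_low = lag_low, lag_high = lag_high,
              stability_min = stability_min, stability_tol_lags = stability_tol_lags,
              scenario = scenario, n_draws = n_draws,
              keep = keep %||% max(1, round(n_draws / 1000)), seed = seed)
  class(cfg) <- "analysis_config"
  cfg
}

#' Save / load an analysis configuration (lossless JSON round trip)
#' @param config an [analysis_config()].
#' @param path JSON file path.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, raw)
}
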