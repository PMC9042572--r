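#' Uniformly sampled hormone/mediator time series
#'
#' The basic signal container used throughout the package: a scalar
#' concentration (or dimensionless) signal on a uniform time grid in minutes
#' since the subject's own sampling start. Missing samples are stored as `NA`,
#' never as zeros.
#'
#' @param v numeric values; `NA` marks a missing sample. Concentration units
#'   must be non-negative.
#' @param t time grid in minutes. If `NULL`, built as `t0 + (0:(n-1)) * dt`.
#'   Must be strictly increasing and uniform to within 1% of `dt`; small
#'   jitter is snapped onto the exact grid.
#' @param dt sampling interval in minutes (default 10, the assay cadence).
#' @param units one of `"ng/l"`, `"nmol/l"`, `"pg/ml"`, `"dimensionless"`.
#' @param name label for the analyte (e.g. `"ACTH"`).
#' @param t0 start time in minutes, used when `t` is `NULL`.
#' @return An object of class `hpa_ts`: a list with fields `name`, `t`, `v`,
#'   `units`, `dt`.
#' @examples
#' acth <- hpa_ts(c(10, 25, 40, 22, 12), dt = 10, units = "ng/l", name = "ACTH")
#' acth
#' @export
hpa_ts <- function(v, t = NULL, dt = 10, units = "dimensionless",
                   name = "series", t0 = 0) {
  units <- match.arg(units, c("ng/l", "nmol/l", "pg/ml", "dimensionless"))
  v <- as.numeric(v)
  if (length(v) < 2L) hpa_stop("a time series needs at least 2 samples", "value_error")
  if (is.null(t)) {
    if (!is_scalar_number(dt) || dt <= 0) hpa_stop("dt must be a positive number", "value_error")
    t <- t0 + (seq_along(v) - 1) * dt
  } else {
    t <- as.numeric(t)
    if (length(t) != length(v)) hpa_stop("t and v must have equal length", "value_error")
    if (any(diff(t) <= 0)) hpa_stop("time grid must be strictly increasing", "grid_error")
    d <- diff(t)
    dt_est <- median(d)
    if (any(abs(d - dt_est) > 0.01 * dt_est)) {
      hpa_stop(sprintf("non-uniform grid: spacing deviates by more than 1%% of dt = %g min", dt_est),
               "grid_error")
    }
    dt <- dt_est
    t <- t[1] + (seq_along(v) - 1) * dt  # snap jitter onto the exact grid
  }
  bad <- !is.na(v) & !is.finite(v)
  if (any(bad)) hpa_stop("values must be finite or NA", "value_error")
  if (units != "dimensionless" && any(v < 0, na.rm = TRUE)) {
    hpa_stop(sprintf("negative %s concentration in '%s'", units, name), "value_error")
  }
  structure(list(name = name, t = t, v = v, units = units, dt = dt),
            class = "hpa_ts")
}

#' @export
print.hpa_ts <- function(x, ...) {
  cat(sprintf("<hpa_ts> %s [%s], %d samples, dt = %g min, span %g-%g min, %d missing\n",
              x$name, x$units, length(x$v), x$dt, x$t[1], x$t[length(x$t)],
              sum(is.na(x$v))))
  invisible(x)
}

#' @export
length.hpa_ts <- function(x) length(x$v)

ts_check_shared_grid <- function(a, b) {
  if (length(a$t) != length(b$t) || max(abs(a$t - b$t)) > 1e-8 * max(1, a$dt)) {
    hpa_stop("series are not on a shared time grid", "value_error")
  }
  invisible(TRUE)
}

#' Resample a series onto a uniform grid by linear interpolation
#'
#' Interpolates linearly onto the uniform grid spanning the original record;
#' the first and last samples are preserved exactly. Interior missing values
#' are interpolated across, and the affected output samples are recorded in
#' the `gaps` attribute.
#'
#' @param ts an [hpa_ts()] series.
#' @param dt_out output sampling interval in minutes (> 0).
#' @return An `hpa_ts` on the new grid; attribute `gaps` holds the output
#'   times that fall inside interpolated gaps (if any).
#' @export
resample_uniform <- function(ts, dt_out) {
  stopifnot(inherits(ts, "hpa_ts"))
  if (!is_scalar_number(dt_out) || dt_out <= 0) {
    hpa_stop("dt_out must be a positive number of minutes", "value_error")
  }
  t0 <- ts$t[1]; t1 <- ts$t[length(ts$t)]
  n_out <- floor((t1 - t0) / dt_out + 1e-9) + 1
  t_new <- t0 + (seq_len(n_out) - 1) * dt_out
  ok <- !is.na(ts$v)
  if (sum(ok) < 2L) hpa_stop("too few observed samples to interpolate", "value_error")
  v_new <- approx(ts$t[ok], ts$v[ok], xout = t_new, rule = 2)$y
  out <- hpa_ts(v_new, t = t_new, units = ts$units, name = ts$name)
  if (any(!ok)) {
    gap_t <- ts$t[!ok]
    in_gap <- vapply(t_new, function(tt) {
      any(abs(tt - gap_t) < ts$dt)
    }, logical(1))
    attr(out, "gaps") <- t_new[in_gap]
  }
  out
}

#' Area under the concentration-time curve
#'
#' Trapezoidal integral of the series over `[t0, t1]`, reported in
#' units x hours (the conventional total-secretion summary). Window endpoints
#' that fall between samples are handled by linear interpolation.
#'
#' @param ts an [hpa_ts()] series without missing values in the window.
#' @param t0,t1 window in minutes within the record span, `t0 < t1`.
#' @return AUC in `units x hours`.
#' @examples
#' flat <- hpa_ts(rep(1, 73), dt = 10)                 # 12 h of constant 1.0
#' area_under_curve(flat, 0, 720)                      # = 12
#' @export
area_under_curve <- function(ts, t0, t1) {
  stopifnot(inherits(ts, "hpa_ts"))
  if (!(t0 < t1)) hpa_stop("t0 must be < t1", "value_error")
  if (t0 < ts$t[1] - 1e-9 || t1 > ts$t[length(ts$t)] + 1e-9) {
    hpa_stop("integration window outside the record span", "range_error")
  }
  near <- ts$t >= t0 - ts$dt & ts$t <= t1 + ts$dt
  if (anyNA(ts$v[near])) hpa_stop("missing values inside the integration window", "value_error")
  inside <- ts$t > t0 & ts$t < t1
  tt <- c(t0, ts$t[inside], t1)
  vv <- approx(ts$t, ts$v, xout = tt)$y
  sum(diff(tt) * (head(vv, -1) + tail(vv, -1)) / 2) / 60
}
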