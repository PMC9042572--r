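#' Pointwise hormone ratio
#'
#' Elementwise ACTH/cortisol ratio on a shared grid; samples with a zero
#' denominator (or a missing operand) are flagged missing.
#'
#' @param a,c series on a shared grid.
#' @return A dimensionless `hpa_ts`.
#' @export
hormone_ratio <- function(a, c) {
  stopifnot(inherits(a, "hpa_ts"), inherits(c, "hpa_ts"))
  ts_check_shared_grid(a, c)
  r <- ifelse(!is.na(c$v) & c$v == 0, NA_real_, a$v / c$v)
  hpa_ts(r, t = a$t, units = "dimensionless", name = paste0(a$name, "/", c$name))
}

#' Rolling (time-dependent) Pearson correlation
#'
#' Centred rolling-window Pearson correlation between two series; window
#' positions that are incomplete at the record ends, or have zero variance,
#' are flagged missing.
#'
#' @param a,c series on a shared grid.
#' @param window window length in minutes (must hold >= 3 samples and fit in
#'   the record).
#' @return A dimensionless `hpa_ts` of correlations in `[-1, 1]`.
#' @export
rolling_correlation <- function(a, c, window) {
  stopifnot(inherits(a, "hpa_ts"), inherits(c, "hpa_ts"))
  ts_check_shared_grid(a, c)
  n <- length(a$v)
  half <- floor(window / (2 * a$dt))
  k <- 2L * half + 1L
  if (k < 3L) hpa_stop("window must span at least 3 samples", "value_error")
  if (k > n) hpa_stop("window longer than the record", "value_error")
  r <- rep(NA_real_, n)
  for (i in (half + 1):(n - half)) {
    wa <- a$v[(i - half):(i + half)]; wc <- c$v[(i - half):(i + half)]
    if (anyNA(wa) || anyNA(wc)) next
    if (sd(wa) == 0 || sd(wc) == 0) next
    r[i] <- cor(wa, wc)
  }
  hpa_ts(r, t = a$t, units = "dimensionless", name = "rolling_r")
}

# analytic signal via the frequency-domain construction; x must be real
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

bandpass_ultradian <- function(v, dt, band) {
  # band edges are periods in minutes; normalised frequency = 2*dt/period
  w <- sort(2 * dt / band)
  w <- pmin(pmax(w, 1e-4), 0.999)
  bf <- signal::butter(2, w, type = "pass")
  signal::filtfilt(bf, v)
}

#' Instantaneous phase synchrony between ACTH and cortisol
#'
#' Both series are z-scored, band-passed to the ultradian band, and their
#' analytic-signal phases extracted; the synchrony trace is
#' `IPS(t) = 1 - |sin((phi_a - phi_c)/2)|`, so identical phases score 1 and
#' antiphase scores 0. Filter edge effects make the first and last samples
#' unreliable, as with any finite-record phase estimate.
#'
#' @param a,c series on a shared grid, no missing values, spanning at least
#'   two ultradian cycles.
#' @param band band-pass edges as periods in minutes.
#' @return A dimensionless `hpa_ts` in `[0, 1]`.
#' @export
instantaneous_phase_synchrony <- function(a, c, band = c(60, 480)) {
  stopifnot(inherits(a, "hpa_ts"), inherits(c, "hpa_ts"))
  ts_check_shared_grid(a, c)
  if (anyNA(a$v) || anyNA(c$v)) hpa_stop("missing values not supported here", "value_error")
  span <- a$t[length(a$t)] - a$t[1]
  if (span < 2 * band[1]) hpa_stop("record shorter than two ultradian cycles", "value_error")
  za <- (a$v - mean(a$v)) / sd(a$v)
  zc <- (c$v - mean(c$v)) / sd(c$v)
  pa <- Arg(analytic_signal(bandpass_ultradian(za, a$dt, band)))
  pc <- Arg(analytic_signal(bandpass_ultradian(zc, c$dt, band)))
  ips <- 1 - abs(sin((pa - pc) / 2))
  hpa_ts(ips, t = a$t, units = "dimensionless", name = "IPS")
}

# Spearman correlation of c against a for every shift of -L..L samples;
# positive shifts compare a[i] with c[i + k] (first argument leading).
spearman_lag_scan <- function(av, cv, L) {
  n <- length(av)
  vapply(-L:L, function(k) {
    if (k >= 0) {
      x <- av[seq_len(n - k)]; y <- cv[seq_len(n - k) + k]
    } else {
      x <- av[seq_len(n + k) - k]; y <- cv[seq_len(n + k)]
    }
    suppressWarnings(cor(x, y, method = "spearman", use = "complete.obs"))
  }, numeric(1))
}

pick_peak_lag <- function(lags, r) {
  ok <- which(is.finite(r))
  peak <- max(r[ok])
  cand <- ok[r[ok] >= peak - 1e-12]
  cand[order(abs(lags[cand]), -sign(lags[cand]))][1]  # ties toward |lag| = 0, then positive
}

#' Time-lagged cross-correlation (TLCC)
#'
#' Spearman correlation between the two series at every shift of a whole
#' sampling step within `[-max_lag, +max_lag]`. Positive peak lag means the
#' first series (ACTH) leads the second (cortisol); ties are broken toward
#' the smallest absolute lag.
#'
#' @param a,c series on a shared grid.
#' @param max_lag maximum lag in minutes, at most one third of the record.
#' @return A list of class `tlcc` with `lags` (minutes), `r`, `peak_lag`
#'   (minutes) and `peak_r`.
#' @export
tlcc <- function(a, c, max_lag = 180) {
  stopifnot(inherits(a, "hpa_ts"), inherits(c, "hpa_ts"))
  ts_check_shared_grid(a, c)
  n <- length(a$v)
  L <- floor(max_lag / a$dt)
  if (L < 1 || L > n / 3) hpa_stop("record too short for the requested max_lag", "value_error")
  r <- spearman_lag_scan(a$v, c$v, L)
  lags <- (-L:L) * a$dt
  i <- pick_peak_lag(lags, r)
  structure(list(lags = lags, r = r, peak_lag = lags[i], peak_r = r[i]),
            class = "tlcc")
}

#' Rolling-window time-lagged cross-correlation (RWTLCC)
#'
#' Recomputes the TLCC in windows advanced by `step`, one row per epoch, so
#' that a stationary association shows as a "vertical stripe" of constant
#' peak lag down the matrix (elapsed time increases downwards).
#'
#' @param a,c series on a shared grid.
#' @param window epoch length in minutes; must hold at least
#'   `2 * max_lag + 3` samples (clamped to the record when longer).
#' @param step epoch advance in minutes.
#' @param max_lag per-epoch lag range in minutes.
#' @return A numeric matrix (epochs x lags) with attributes `lags` (minutes)
#'   and `epoch_start` (minutes).
#' @export
rwtlcc <- function(a, c, window = 240, step = 30, max_lag = 90) {
  stopifnot(inherits(a, "hpa_ts"), inherits(c, "hpa_ts"))
  ts_check_shared_grid(a, c)
  n <- length(a$v)
  L <- floor(max_lag / a$dt)
  w <- min(floor(window / a$dt) + 1L, n)
  s <- max(1L, round(step / a$dt))
  if (L < 1 || w < 2 * L + 3) {
    hpa_stop("window must hold at least 2*max_lag + 3 samples", "value_error")
  }
  starts <- seq(1L, n - w + 1L, by = s)
  m <- t(vapply(starts, function(i) {
    spearman_lag_scan(a$v[i:(i + w - 1L)], c$v[i:(i + w - 1L)], L)
  }, numeric(2L * L + 1L)))
  attr(m, "lags") <- (-L:L) * a$dt
  attr(m, "epoch_start") <- a$t[starts]
  m
}

moving_average <- function(v, k) {
  # centred moving average with shrinking windows at the record ends
  n <- length(v)
  half <- floor(k / 2)
  vapply(seq_len(n), function(i) {
    mean(v[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Estimate the ultradian period of a pulsatile series
#'
#' The series is detrended by subtracting a 6-hour centred moving average;
#' the period is the lag of the first prominent positive autocorrelation
#' peak. When the autocorrelation has no such peak (e.g. only two pulses in
#' the record) the estimate falls back to the mean peak-to-peak interval of
#' the detected pulses.
#'
#' @param ts an `hpa_ts` holding at least two pulses/cycles.
#' @param detrend_window moving-average detrend window, minutes.
#' @param min_acf minimum autocorrelation for a peak to count as prominent.
#' @return Period estimate in minutes.
#' @export
estimate_ultradian_period <- function(ts, detrend_window = 360, min_acf = 0.15) {
  stopifnot(inherits(ts, "hpa_ts"))
  if (anyNA(ts$v)) hpa_stop("missing values not supported here", "value_error")
  if (sd(ts$v) == 0) hpa_stop("constant series has no defined period", "undefined_period")
  x <- ts$v - moving_average(ts$v, floor(detrend_window / ts$dt) + 1L)
  n <- length(x)
  ac <- as.numeric(stats::acf(x, lag.max = n - 1L, plot = FALSE)$acf)
  # local maxima of the autocorrelation at lag >= 2 samples
  for (i in 3:(n - 1)) {
    if (ac[i] > ac[i - 1] && ac[i] >= ac[i + 1] && ac[i] >= min_acf) {
      return((i - 1) * ts$dt)
    }
  }
  pk <- find_pulses(ts)
  if (length(pk) >= 2L) return(mean(diff(ts$t[pk])))
  hpa_stop("no repeating structure: period undefined", "undefined_period")
}

# indices of local maxima passing the prominence and separation rules;
# record endpoints are never counted (their prominence is undefined)
find_pulses <- function(ts, prominence_frac = 0.2, separation = 60) {
  v <- ts$v
  n <- length(v)
  rng <- diff(range(v, na.rm = TRUE))
  if (!is.finite(rng) || rng == 0) return(integer(0))
  cand <- which(vapply(2:(n - 1), function(i) {
    !is.na(v[i]) && v[i] > v[i - 1] && v[i] >= v[i + 1]
  }, logical(1))) + 1L
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) peak_prominence(v, i), numeric(1))
  cand <- cand[prom >= prominence_frac * rng]
  if (length(cand) <= 1L) return(cand)
  # greedy enforcement of the minimum separation, tallest peaks first
  keep <- integer(0)
  for (i in cand[order(-v[cand])]) {
    if (!length(keep) || all(abs(ts$t[i] - ts$t[keep]) >= separation)) {
      keep <- c(keep, i)
    }
  }
  sort(keep)
}

# topographic prominence: height above the higher of the two key saddles
peak_prominence <- function(v, i) {
  n <- length(v)
  left <- v[seq_len(i - 1)]
  higher_l <- which(left > v[i])
  lmin <- if (length(higher_l)) min(v[(max(higher_l) + 1):(i - 1)], v[i]) else min(left, v[i])
  right <- v[(i + 1):n]
  higher_r <- which(right > v[i])
  rmin <- if (length(higher_r)) min(v[(i + 1):(i + min(higher_r) - 1)], v[i]) else min(right, v[i])
  v[i] - max(lmin, rmin)
}

#' Count prominent pulses in a hormone record
#'
#' Local maxima with topographic prominence of at least `prominence_frac` of
#' the trace range and pairwise separation of at least `separation` minutes.
#' Extrema sitting exactly on the record boundary are not counted.
#'
#' @param ts an `hpa_ts` spanning at least 2 hours.
#' @param prominence_frac minimum prominence as a fraction of the range.
#' @param separation minimum pulse spacing in minutes.
#' @return Integer pulse count (0 is valid).
#' @export
count_pulses <- function(ts, prominence_frac = 0.2, separation = 60) {
  stopifnot(inherits(ts, "hpa_ts"))
  if (ts$t[length(ts$t)] - ts$t[1] < 120) hpa_stop("record shorter than 2 h", "value_error")
  length(find_pulses(ts, prominence_frac, separation))
}

#' Compute the full synchrony battery for one subject
#'
#' Convenience wrapper producing everything the phenotype classifier needs:
#' hormone ratio, rolling Pearson correlation, IPS, TLCC (curve and peak),
#' RWTLCC matrix, synchrony stability, ultradian period (of cortisol) and
#' cortisol pulse count.
#'
#' @param profile a [subject_profile()].
#' @param config an [analysis_config()].
#' @return A list of class `sync_metrics`.
#' @export
compute_sync_metrics <- function(profile, config = analysis_config()) {
  stopifnot(inherits(profile, "subject_profile"))
  a <- profile$acth; c <- profile$cortisol
  n <- length(a$v)
  ml <- min(config$max_lag, floor(n / 3) * a$dt)
  tl <- tlcc(a, c, max_lag = ml)
  rw <- rwtlcc(a, c, window = config$rwtlcc_window, step = config$rwtlcc_step,
               max_lag = config$rwtlcc_max_lag)
  period <- tryCatch(estimate_ultradian_period(c),
                     hpadyn_undefined_period = function(e) NA_real_)
  structure(list(
    ratio = hormone_ratio(a, c),
    rolling_r = rolling_correlation(a, c, config$rolling_window),
    ips = instantaneous_phase_synchrony(a, c, config$band),
    tlcc_lags = tl$lags, tlcc_r = tl$r,
    peak_lag = tl$peak_lag, peak_r = tl$peak_r,
    rwtlcc = rw,
    stability = synchrony_stability(rw, config$stability_tol_lags),
    period = period,
    n_pulses = count_pulses(c, config$pulse_prominence, config$pulse_separation)
  ), class = "sync_metrics")
}
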