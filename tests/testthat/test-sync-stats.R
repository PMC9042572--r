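test_that("hormone ratio handles zeros and scales linearly", {
  a <- hpa_ts(c(1, 2, 3, 4), dt = 10)
  expect_equal(hormone_ratio(a, a)$v, rep(1, 4))
  c0 <- hpa_ts(c(1, 0, 3, 4), dt = 10)
  r <- hormone_ratio(a, c0)
  expect_true(is.na(r$v[2]) && !anyNA(r$v[-2]))
  k <- 3.7
  ak <- hpa_ts(k * a$v, t = a$t)
  expect_equal(hormone_ratio(ak, c0)$v[-2], k * r$v[-2])
  expect_error(hormone_ratio(a, hpa_ts(1:5, dt = 10)), class = "hpadyn_value_error")
})

test_that("rolling correlation tracks exact linear relationships", {
  a <- make_subject(2)$acth
  lin <- hpa_ts(2 * a$v + 1, t = a$t)
  r <- rolling_correlation(a, lin, window = 60)
  expect_equal(r$v[!is.na(r$v)], rep(1, sum(!is.na(r$v))), tolerance = 1e-12)
  neg <- hpa_ts(max(a$v) - a$v, t = a$t)
  rn <- rolling_correlation(a, neg, window = 60)
  expect_equal(rn$v[!is.na(rn$v)], rep(-1, sum(!is.na(rn$v))), tolerance = 1e-12)
  # zero-variance windows are flagged missing, and the ends are incomplete
  flat <- hpa_ts(rep(5, length(a$v)), t = a$t)
  expect_true(all(is.na(rolling_correlation(a, flat, 60)$v)))
  expect_true(is.na(r$v[1]) && is.na(r$v[length(r$v)]))
  expect_error(rolling_correlation(a, lin, window = 1e5), class = "hpadyn_value_error")
})

test_that("instantaneous phase synchrony maps phase offsets as 1 - |sin(d/2)|", {
  interior <- function(x) x$v[8:(length(x$v) - 7)]
  a <- sinus_ts(period = 180, duration = 1440)
  expect_true(all(interior(instantaneous_phase_synchrony(a, a)) >= 0.99))
  anti <- sinus_ts(period = 180, duration = 1440, phase = pi)
  expect_true(all(interior(instantaneous_phase_synchrony(a, anti)) <= 0.05))
  for (delta in c(pi / 6, pi / 3, pi / 2)) {
    off <- sinus_ts(period = 180, duration = 1440, phase = -delta)
    ips <- interior(instantaneous_phase_synchrony(a, off))
    expect_equal(mean(ips), 1 - abs(sin(delta / 2)), tolerance = 0.02)
  }
  short <- sinus_ts(period = 180, duration = 100)
  expect_error(instantaneous_phase_synchrony(short, short), class = "hpadyn_value_error")
})

test_that("TLCC recovers exact shifts with the stated sign convention", {
  a <- make_subject(3)$acth
  n <- length(a$v)
  c3 <- hpa_ts(c(a$v[1:3], a$v[1:(n - 3)]), t = a$t)  # a leads c by 3 samples
  tl <- tlcc(a, c3, max_lag = 180)
  expect_equal(tl$peak_lag, 30)
  expect_equal(tl$peak_r, 1, tolerance = 1e-12)
  expect_equal(tlcc(c3, a, 180)$peak_lag, -tl$peak_lag)
  expect_error(tlcc(a, c3, max_lag = 700), class = "hpadyn_value_error")
})

test_that("TLCC equals a brute-force per-lag Spearman scan", {
  prof <- make_subject(17)
  tl <- tlcc(prof$acth, prof$cortisol, max_lag = 180)
  expect_equal(tl$r, oracle_lag_scan(prof$acth$v, prof$cortisol$v, 18),
               tolerance = 1e-12)
  # degenerate lag range equals the global Spearman correlation
  tl0 <- tlcc(prof$acth, prof$cortisol, max_lag = 10)
  expect_equal(tl0$r[2], cor(prof$acth$v, prof$cortisol$v, method = "spearman"))
  expect_true(all(abs(tl$r) <= 1))
})

test_that("RWTLCC shows stripes for stationary pairs and switches on lag changes", {
  a <- make_subject(23)$acth
  n <- length(a$v)
  cs <- hpa_ts(c(a$v[1:2], a$v[1:(n - 2)]), t = a$t)  # stationary 2-sample lag
  m <- rwtlcc(a, cs, window = 240, step = 30, max_lag = 90)
  args <- apply(m, 1, function(r) attr(m, "lags")[which.max(r)])
  expect_true(all(args == 20))  # one vertical stripe
  # lag switching from 0 to 3 samples at the midpoint
  half <- floor(n / 2)
  cswitch <- hpa_ts(c(a$v[1:half], a$v[(half - 2):(n - 3)]), t = a$t)
  ms <- rwtlcc(a, cswitch, window = 240, step = 30, max_lag = 90)
  args2 <- apply(ms, 1, function(r) attr(ms, "lags")[which.max(r)])
  expect_equal(args2[1], 0)
  expect_equal(args2[length(args2)], 30)
  # a window covering the whole record reduces to the plain TLCC
  m1 <- rwtlcc(a, cs, window = 1e6, step = 1e6, max_lag = 90)
  expect_equal(nrow(m1), 1)
  expect_equal(as.numeric(m1[1, ]), tlcc(a, cs, max_lag = 90)$r)
  expect_error(rwtlcc(a, cs, window = 100, step = 30, max_lag = 90),
               class = "hpadyn_value_error")
})

test_that("period estimation finds sinusoid and sparse-pulse periods", {
  s <- sinus_ts(period = 180, duration = 720)
  expect_lte(abs(estimate_ultradian_period(s) - 180), 10)
  two <- gauss_ts(c(150, 480), amp = 10, sd = 25)
  expect_lte(abs(estimate_ultradian_period(two) - 330), 10)
  flat <- hpa_ts(rep(2, 73), dt = 10)
  expect_error(estimate_ultradian_period(flat), class = "hpadyn_undefined_period")
})

test_that("pulse counting respects prominence, separation and endpoints", {
  three <- gauss_ts(c(120, 300, 480), amp = 10, sd = 20)
  expect_equal(count_pulses(three), 3)
  ramp <- hpa_ts(seq(0, 10, length.out = 73), dt = 10)
  expect_equal(count_pulses(ramp), 0)  # boundary extrema are not pulses
  flat <- hpa_ts(rep(1, 73), dt = 10)
  expect_equal(count_pulses(flat), 0)
  # affine invariance of period and count
  s <- make_subject(31)$cortisol
  s2 <- hpa_ts(4 * s$v + 100, t = s$t)
  expect_equal(count_pulses(s2), count_pulses(s))
  expect_equal(estimate_ultradian_period(s2), estimate_ultradian_period(s))
  short <- hpa_ts(c(1, 2, 1), dt = 10)
  expect_error(count_pulses(short), class = "hpadyn_value_error")
})
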