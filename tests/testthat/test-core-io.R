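test_that("time-series container validates its grid and values", {
  ts <- hpa_ts(c(1, 2, 3), dt = 10, units = "nmol/l")
  expect_equal(ts$t, c(0, 10, 20))
  expect_equal(ts$dt, 10)
  # jitter within 1% of dt is snapped onto the exact grid
  tj <- hpa_ts(c(1, 2, 3), t = c(0, 10.05, 20.02))
  expect_equal(diff(tj$t), c(10.01, 10.01), tolerance = 1e-6)
  expect_error(hpa_ts(c(1, 2, 3), t = c(0, 10, 25)), class = "hpadyn_grid_error")
  expect_error(hpa_ts(c(1, -2, 3), dt = 10, units = "ng/l"), class = "hpadyn_value_error")
  expect_error(hpa_ts(1), class = "hpadyn_value_error")
  expect_silent(hpa_ts(c(1, NA, 3), dt = 10, units = "pg/ml"))  # missing is flagged, not zeroed
})

test_that("panel CSV round trip preserves profiles field by field", {
  p <- gen_cabg_profile(regime_spec("two_pulse"), seed = 3)
  p <- gen_cytokine_traces(p, seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(list(p), path)
  back <- read_panel_csv(path)
  expect_length(back, 1)
  q <- back[[1]]
  expect_equal(q$subject_id, p$subject_id)
  expect_equal(q$acth$v, p$acth$v, tolerance = 1e-6)
  expect_equal(q$cortisol$v, p$cortisol$v, tolerance = 1e-6)
  expect_setequal(names(q$cytokines), names(p$cytokines))
  expect_equal(q$cytokines$IL6$v, p$cytokines$IL6$v, tolerance = 1e-6)
  expect_equal(q$surgery_window, p$surgery_window)
  expect_equal(q$true_regime, p$true_regime)
  expect_equal(q$acth$units, "ng/l")
})

test_that("panel readers reject malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(t_min = c(0, 10, 20)), path, row.names = FALSE)
  expect_error(read_panel_csv(path, format = "wide"), class = "hpadyn_schema_error")
  write.csv(data.frame(a = 1:3, b = 4:6), path, row.names = FALSE)
  expect_error(read_panel_csv(path), class = "hpadyn_schema_error")
})

test_that("wide-format reader builds a profile from analyte columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(t_min = seq(0, 120, 10), ACTH = 1:13, cortisol = 13:1,
                       IL6 = rep(2, 13)), path, row.names = FALSE)
  p <- read_panel_csv(path, format = "wide")[[1]]
  expect_equal(p$acth$v, as.numeric(1:13))
  expect_equal(p$cortisol$units, "nmol/l")
  expect_named(p$cytokines, "IL6")
})

test_that("resampling interpolates linearly and preserves endpoints", {
  ts <- hpa_ts(c(0, 10), t = c(0, 10))
  out <- resample_uniform(ts, 5)
  expect_equal(out$v, c(0, 5, 10))
  # idempotence at the native dt
  ts2 <- hpa_ts(c(3, 1, 4, 1, 5), dt = 10)
  expect_equal(resample_uniform(ts2, 10)$v, ts2$v)
  # interior gaps are interpolated across and flagged
  tsg <- hpa_ts(c(1, 2, NA, 4, 5), dt = 10)
  outg <- resample_uniform(tsg, 10)
  expect_equal(outg$v, c(1, 2, 3, 4, 5))
  expect_true(20 %in% attr(outg, "gaps"))
  expect_error(resample_uniform(ts, 0), class = "hpadyn_value_error")
})

test_that("resampling commutes with affine rescaling of values", {
  ts <- make_subject(5)$cortisol
  a <- 2.5; b <- 7
  r1 <- resample_uniform(hpa_ts(a * ts$v + b, t = ts$t), 5)
  r2 <- resample_uniform(hpa_ts(ts$v, t = ts$t), 5)
  expect_equal(r1$v, a * r2$v + b, tolerance = 1e-12)
})

test_that("AUC matches closed forms and a fine-grid Riemann oracle", {
  flat <- hpa_ts(rep(1, 73), dt = 10)
  expect_equal(area_under_curve(flat, 0, 720), 12)
  ramp <- hpa_ts(seq(0, 10, length.out = 61), dt = 10)  # 0 -> 10 over 10 h
  expect_equal(area_under_curve(ramp, 0, 600), 50)
  # pulsatile trace vs Riemann sum on a 0.01-min grid
  ts <- gauss_ts(c(150, 400, 600))
  fine_t <- seq(0, 720, by = 0.01)
  fine_v <- approx(ts$t, ts$v, xout = fine_t)$y
  riemann <- sum(fine_v[-1] * 0.01) / 60
  expect_equal(area_under_curve(ts, 0, 720), riemann, tolerance = 1e-3)
  expect_error(area_under_curve(flat, -10, 720), class = "hpadyn_range_error")
})

test_that("AUC is additive over adjacent windows", {
  ts <- make_subject(7)$cortisol
  lhs <- area_under_curve(ts, 0, 275) + area_under_curve(ts, 275, 720)
  expect_equal(lhs, area_under_curve(ts, 0, 720), tolerance = 1e-9)
})

test_that("analysis config serialises losslessly", {
  cfg <- analysis_config(max_lag = 120, scenario = "fixed_both", n_draws = 500)
  path <- withr::local_tempfile(fileext = ".json")
  save_config(cfg, path)
  expect_equal(load_config(path), cfg)
})
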