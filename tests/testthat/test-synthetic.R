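test_that("generation is seeded and deterministic", {
  p1 <- gen_healthy_profile(seed = 5)
  p2 <- gen_healthy_profile(seed = 5)
  expect_identical(p1, p2)
  q1 <- gen_cabg_profile(regime_spec("multiple_pulse"), seed = 5)
  q2 <- gen_cabg_profile(regime_spec("multiple_pulse"), seed = 5)
  expect_identical(q1, q2)
  expect_false(identical(p1$acth$v, gen_healthy_profile(seed = 6)$acth$v))
})

test_that("regime specs validate their fields", {
  expect_error(regime_spec("two_pulse", pulse_period = -5), class = "hpadyn_value_error")
  expect_error(regime_spec("control", noise_sd_frac = 0.9), class = "hpadyn_value_error")
  expect_error(regime_spec("two_pulse", duration = 400), class = "hpadyn_value_error")
  expect_error(gen_cabg_profile(regime_spec("control"), seed = 1), class = "hpadyn_value_error")
  expect_error(gen_healthy_profile(regime_spec("control", duration = 719)),
               class = "hpadyn_value_error")
})

test_that("zero-noise profiles equal the noiseless model output exactly", {
  spec <- regime_spec("control", noise_sd_frac = 0)
  p <- gen_healthy_profile(spec, seed = 8)
  sim <- simulate_cortisol(control_params(), p$acth,
                           c_obs0 = steady_state_cortisol(control_params(), p$acth$v[1]))
  expect_equal(p$cortisol$v, sim$C, tolerance = 1e-12)
  acth <- p$acth
  cv0 <- gen_model_cortisol(control_params(), acth, noise_sd_frac = 0, seed = 3)
  cv1 <- gen_model_cortisol(control_params(), acth, noise_sd_frac = 0, seed = 99)
  expect_identical(cv0$v, cv1$v)  # no hidden randomness at zero noise
})

test_that("multiplicative noise has the stated relative spread", {
  acth <- hpa_ts(rep(40, 20001), dt = 1, units = "ng/l")
  cv <- gen_model_cortisol(control_params(), acth, noise_sd_frac = 0.05, seed = 4)
  clean <- gen_model_cortisol(control_params(), acth, noise_sd_frac = 0, seed = 4)
  rel <- cv$v / clean$v - 1
  expect_equal(sd(rel), 0.05, tolerance = 0.05)
})

test_that("healthy profiles show ultradian periodicity in the stated band", {
  for (s in 1:5) {
    p <- gen_healthy_profile(seed = 40 + s)
    per <- estimate_ultradian_period(p$cortisol)
    expect_gte(per, 150); expect_lte(per, 180)
  }
})

test_that("disrupted regimes produce their defining cortisol morphology", {
  for (s in 1:5) {
    two <- gen_cabg_profile(regime_spec("two_pulse"), seed = 50 + s)
    expect_equal(count_pulses(two$cortisol), 2)
    per <- estimate_ultradian_period(two$cortisol)
    expect_gte(per, 300 - 10); expect_lte(per, 360 + 10)
    one <- gen_cabg_profile(regime_spec("single_pulse"), seed = 50 + s)
    expect_equal(count_pulses(one$cortisol), 1)
    multi <- gen_cabg_profile(regime_spec("multiple_pulse"), seed = 50 + s)
    expect_gte(count_pulses(multi$cortisol), 3)
    expect_false(is.null(two$surgery_window))
    expect_equal(multi$true_regime, "multiple_pulse")
  }
})

test_that("all generated concentration series are non-negative", {
  panel <- gen_panel(n_per_regime = 1, seed = 77, cytokines = TRUE)
  for (p in panel) {
    expect_true(all(p$acth$v >= 0) && all(p$cortisol$v >= 0))
    for (cy in p$cytokines) expect_true(all(cy$v >= 0))
  }
})

test_that("cytokine responses start in the second half of surgery", {
  p <- gen_cabg_profile(regime_spec("single_pulse"), seed = 9)
  p <- gen_cytokine_traces(p, seed = 10)
  midpoint <- mean(p$surgery_window)
  for (nm in c("IL6", "TNFa", "IL10", "IL8")) {
    cy <- p$cytokines[[nm]]
    expect_lt(max(cy$v[cy$t <= midpoint]), 0.05 * max(cy$v))
  }
  # zero gains give flat baselines
  p0 <- gen_cytokine_traces(gen_cabg_profile(regime_spec("two_pulse"), seed = 9),
                            seed = 10, gains = list(IL6 = 0, TNFa = 0, IL10 = 0, IL8 = 0))
  for (cy in p0$cytokines) expect_lt(diff(range(cy$v)), 0.2)
  # coupling adds a disturbance proportional to the mediator trace
  base <- gen_cabg_profile(regime_spec("two_pulse"), seed = 9)
  cpl <- gen_cytokine_traces(base, coupling = list(IL6 = 0.7), seed = 10)
  unc <- gen_cytokine_traces(base, coupling = list(), seed = 10)
  expect_equal(cpl$cortisol$v - unc$cortisol$v, 0.7 * cpl$cytokines$IL6$v,
               tolerance = 1e-9)
  nosw <- subject_profile("x", base$acth, base$cortisol)
  expect_error(gen_cytokine_traces(nosw, seed = 1), class = "hpadyn_state_error")
})

test_that("generator calibration: post-surgical secretion totals scale as expected", {
  ctrl <- sapply(1:6, function(s) {
    p <- gen_healthy_profile(seed = 700 + s)
    c(area_under_curve(p$acth, 0, 720), area_under_curve(p$cortisol, 0, 720))
  })
  cabg <- sapply(1:6, function(s) {
    regs <- c("two_pulse", "multiple_pulse", "single_pulse")
    rowMeans(sapply(regs, function(rg) {
      p <- gen_cabg_profile(regime_spec(rg), seed = 700 + s)
      c(area_under_curve(p$acth, 0, 720), area_under_curve(p$cortisol, 0, 720))
    }))
  })
  acth_ratio <- mean(cabg[1, ]) / mean(ctrl[1, ])
  cort_ratio <- mean(cabg[2, ]) / mean(ctrl[2, ])
  expect_gte(acth_ratio, 4.5); expect_lte(acth_ratio, 8)
  expect_gte(cort_ratio, 1.6); expect_lte(cort_ratio, 3)
})
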