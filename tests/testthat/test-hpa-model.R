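test_that("Hill drive hits its landmarks", {
  for (m in 1:4) expect_equal(hill_drive(50.28, 50.28, m), 0.5)
  expect_equal(hill_drive(0, 50.28, 2), 0)
  expect_equal(hill_drive(3 * 7, 7, 2), 0.9)  # A = 3 K_A, m = 2 -> 9/10
  expect_error(hill_drive(-1, 50, 2), class = "hpadyn_value_error")
})

test_that("parameter validation enforces the compartment ordering", {
  expect_error(model_params(1, 1, 100, 50, 40), class = "hpadyn_value_error")
  expect_error(model_params(1, 1, 10, 50, 40, m = 0.5), class = "hpadyn_value_error")
  expect_error(model_params(-1, 1, 10, 50, 40), class = "hpadyn_value_error")
  expect_s3_class(model_params(1, 1, 10, 50, 40), "model_params")
})

test_that("initial state splits quasi-equilibrium fast and clamped slow", {
  # constant ACTH at half-max drive
  acth <- hpa_ts(rep(50, 10), dt = 10, units = "ng/l")
  p <- model_params(p_f = 1, p_s = 1, lambda_f = 10, lambda_s = 100, K_A = 50, m = 2)
  expect_equal(unname(initial_state(p, acth, 100)), c(5, 95))
  expect_equal(unname(initial_state(p, acth, 3)), c(5, 0))   # clamp branch
  z <- hpa_ts(rep(0, 10), dt = 10, units = "ng/l")
  expect_equal(unname(initial_state(p, z, 42)), c(0, 42))    # zero-drive limit
})

test_that("zero-input simulation reproduces the homogeneous decay", {
  z <- hpa_ts(rep(0, 100), dt = 10, units = "ng/l")
  p <- model_params(2, 1, 6, 150, 50, 2)
  sim <- simulate_cortisol(p, z, state0 = c(50, 100))
  anal <- 50 * exp(-sim$t / 6) + 100 * exp(-sim$t / 150)
  expect_lt(max(abs(sim$C - anal)) / max(anal), 1e-6)
})

test_that("constant input at equilibrium is a fixed point", {
  p <- model_params(2, 1, 6, 150, 50, 2)
  acth <- hpa_ts(rep(75, 50), dt = 10, units = "ng/l")
  h <- hill_drive(75, 50, 2)
  eq <- c(p$p_f * p$lambda_f * h, p$p_s * p$lambda_s * h)
  sim <- simulate_cortisol(p, acth, state0 = eq)
  expect_equal(sim$C, rep(sum(eq), length(sim$t)), tolerance = 1e-9)
})

test_that("simulation converges to the closed-form steady state", {
  p <- model_params(2, 1, 6, 60, 50, 2)
  expect_equal(steady_state_cortisol(model_params(1, 0.5, 10, 100, 50, 1), 50), 30)
  expect_equal(steady_state_cortisol(p, 0), 0)
  acth <- hpa_ts(rep(40, 80), dt = 10, units = "ng/l")  # 790 min > 10 lambda_s
  sim <- simulate_cortisol(p, acth, c_obs0 = 0)
  ss <- steady_state_cortisol(p, 40)
  expect_lt(abs(sim$C[length(sim$C)] - ss) / ss, 1e-3)
})

test_that("integrator matches a fine-step reference on pulsatile input", {
  skip_if_not_installed("deSolve")
  prof <- make_subject(11)
  p <- control_params()
  sim <- simulate_cortisol(p, prof$acth, c_obs0 = 150)
  afun <- approxfun(prof$acth$t, prof$acth$v, rule = 2)
  H <- function(tt) hill_drive(pmax(afun(tt - p$delay), 0), p$K_A, p$m)
  rhs <- function(tt, y, parms) {
    list(c(-y[1] / p$lambda_f + p$p_f * H(tt), -y[2] / p$lambda_s + p$p_s * H(tt)))
  }
  ref <- deSolve::ode(initial_state(p, prof$acth, 150), prof$acth$t, rhs, NULL,
                      method = "ode45", rtol = 1e-10, atol = 1e-10)
  refC <- ref[, 2] + ref[, 3]
  expect_lt(max(abs(sim$C - refC)) / max(refC), 1e-5)
})

test_that("structural properties: positivity, linearity, monotonicity, superposition", {
  prof <- make_subject(13)
  p <- model_params(5, 0.5, 8, 200, 50, 2)
  sim <- simulate_cortisol(p, prof$acth, c_obs0 = 100)
  expect_true(all(sim$C_f >= 0) && all(sim$C_s >= 0))
  expect_equal(sim$C, sim$C_f + sim$C_s, tolerance = 1e-12)
  # doubling production doubles the zero-initial-state response
  p2 <- model_params(10, 1, 8, 200, 50, 2)
  s1 <- simulate_cortisol(p, prof$acth, state0 = c(0, 0))
  s2 <- simulate_cortisol(p2, prof$acth, state0 = c(0, 0))
  expect_equal(s2$C, 2 * s1$C, tolerance = 1e-9)
  # pointwise-larger ACTH gives pointwise-larger-or-equal cortisol
  bigger <- hpa_ts(prof$acth$v * 1.3, t = prof$acth$t, units = "ng/l")
  s3 <- simulate_cortisol(p, bigger, state0 = c(0, 0))
  expect_true(all(s3$C >= s1$C - 1e-9))
  # compartments simulated separately sum to the joint simulation
  pf_only <- model_params(5, 0, 8, 200, 50, 2)
  ps_only <- model_params(0, 0.5, 8, 200, 50, 2)
  sf <- simulate_cortisol(pf_only, prof$acth, state0 = c(20, 0))
  ss <- simulate_cortisol(ps_only, prof$acth, state0 = c(0, 80))
  sj <- simulate_cortisol(p, prof$acth, state0 = c(20, 80))
  expect_equal(sf$C_f + ss$C_s, sj$C, tolerance = 1e-9)
})

test_that("simulation rejects inputs that do not span the output grid", {
  acth <- hpa_ts(rep(10, 10), dt = 10, units = "ng/l")
  expect_error(simulate_cortisol(control_params(), acth, t_out = seq(0, 200, 10)),
               class = "hpadyn_range_error")
})
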