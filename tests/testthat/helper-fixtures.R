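# shared fixture builders; everything is generated in code at test time

sinus_ts <- function(period = 180, duration = 720, dt = 10, phase = 0,
                     amp = 1, offset = 2, units = "dimensionless") {
  t <- seq(0, duration, by = dt)
  hpa_ts(offset + amp * sin(2 * pi * t / period + phase), t = t, units = units)
}

gauss_ts <- function(centers, duration = 720, dt = 10, amp = 10, sd = 20,
                     baseline = 1) {
  t <- seq(0, duration, by = dt)
  hpa_ts(pulse_train(t, centers, amp, sd, baseline), t = t)
}

# 12 h noisy pulsatile ACTH + model cortisol, the standard synthetic subject
make_subject <- function(seed = 1, n_pulses = 3, noise = 0.05) {
  withr::with_seed(seed, {
    t <- seq(0, 720, by = 10)
    centers <- sort(runif(n_pulses, 80, 640))
    av <- pulse_train(t, centers, runif(n_pulses, 40, 70), 15, 8)
    av <- pmax(av * (1 + rnorm(length(av), 0, noise)) + rnorm(length(av), 0, 30 * noise), 0.5)
    acth <- hpa_ts(av, t = t, units = "ng/l", name = "ACTH")
    cort <- gen_model_cortisol(control_params(), acth, noise_sd_frac = noise,
                               seed = seed + 1)
    subject_profile(paste0("s", seed), acth, cort)
  })
}

# independent Spearman-scan oracle: rank transform + explicit Pearson formula,
# written without reference to the package's lag machinery
oracle_lag_scan <- function(av, cv, L) {
  pearson <- function(x, y) {
    xm <- x - mean(x); ym <- y - mean(y)
    sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
  }
  n <- length(av)
  sapply(-L:L, function(k) {
    if (k >= 0) { x <- av[1:(n - k)]; y <- cv[(1 + k):n] }
    else        { x <- av[(1 - k):n]; y <- cv[1:(n + k)] }
    pearson(rank(x), rank(y))
  })
}
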