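#' Specification of a synthetic-profile regime
#'
#' Describes one generating regime: the intact control profile (regular
#' ultradian pulsatility with circadian-modulated amplitude) or one of the
#' three post-surgical disruption regimes — two large slow pulses, multiple
#' fast pulses with strong peak dissociation, or a single large excursion
#' with unstable synchrony.
#'
#' @param regime `"control"`, `"two_pulse"`, `"multiple_pulse"` or
#'   `"single_pulse"`.
#' @param pulse_period target inter-pulse interval, minutes.
#' @param n_pulses pulse count for the pulse-limited regimes.
#' @param acth_peak_scale ACTH pulse amplitude multiplier relative to the
#'   control amplitude.
#' @param cortisol_lag extra ACTH-to-cortisol dissociation lag, minutes,
#'   applied on top of the model's input delay.
#' @param synchrony_mode `"stable"` (no extra lag structure), `"partial"`
#'   (the extra lag applies from the end of surgery onwards) or `"unstable"`
#'   (a fresh random lag per 2 h epoch).
#' @param noise_sd_frac multiplicative measurement-noise SD as a fraction of
#'   the signal, in `[0, 0.5]`.
#' @param duration record length, minutes (24 h controls, 12 h patients).
#' @return A list of class `regime_spec` with regime-calibrated defaults for
#'   any argument left `NULL`.
#' @export
regime_spec <- function(regime = c("control", "two_pulse", "multiple_pulse", "single_pulse"),
                        pulse_period = NULL, n_pulses = NULL,
                        acth_peak_scale = NULL, cortisol_lag = NULL,
                        synchrony_mode = NULL, noise_sd_frac = 0.05,
                        duration = NULL) {
  regime <- match.arg(regime)
  def <- switch(regime,
    control        = list(pulse_period = 165, n_pulses = NA, acth_peak_scale = 1,
                          cortisol_lag = 0, synchrony_mode = "stable", duration = 1440),
    two_pulse      = list(pulse_period = 330, n_pulses = 2, acth_peak_scale = 10,
                          cortisol_lag = 0, synchrony_mode = "stable", duration = 720),
    multiple_pulse = list(pulse_period = 120, n_pulses = 6, acth_peak_scale = 8,
                          cortisol_lag = 100, synchrony_mode = "partial", duration = 720),
    single_pulse   = list(pulse_period = NA, n_pulses = 1, acth_peak_scale = 12,
                          cortisol_lag = 77, synchrony_mode = "unstable", duration = 720))
  spec <- list(regime = regime,
               pulse_period = pulse_period %||% def$pulse_period,
               n_pulses = n_pulses %||% def$n_pulses,
               acth_peak_scale = acth_peak_scale %||% def$acth_peak_scale,
               cortisol_lag = cortisol_lag %||% def$cortisol_lag,
               synchrony_mode = synchrony_mode %||% def$synchrony_mode,
               noise_sd_frac = noise_sd_frac,
               duration = duration %||% def$duration)
  if (!spec$synchrony_mode %in% c("stable", "partial", "unstable")) {
    hpa_stop("synchrony_mode must be stable, partial or unstable", "value_error")
  }
  if (spec$noise_sd_frac < 0 || spec$noise_sd_frac > 0.5) {
    hpa_stop("noise_sd_frac must lie in [0, 0.5]", "value_error")
  }
  if (!is.na(spec$pulse_period)) {
    if (spec$pulse_period <= 0) hpa_stop("pulse_period must be > 0", "value_error")
    if (regime != "single_pulse" && spec$duration < 2 * spec$pulse_period) {
      hpa_stop("duration must cover at least two pulse periods", "value_error")
    }
  }
  structure(spec, class = "regime_spec")
}

#' Sum-of-Gaussians pulse train
#'
#' Builds a pulsatile trace as Gaussian bumps on a constant baseline — the
#' waveform used for all synthetic ACTH records.
#'
#' @param t time grid, minutes.
#' @param centers pulse centre times, minutes.
#' @param amplitudes peak heights (recycled).
#' @param width_sd Gaussian SD, minutes.
#' @param baseline additive baseline.
#' @return Numeric vector on `t`.
#' @export
pulse_train <- function(t, centers, amplitudes, width_sd = 15, baseline = 0) {
  amplitudes <- rep_len(amplitudes, length(centers))
  v <- rep(baseline, length(t))
  for (i in seq_along(centers)) {
    v <- v + amplitudes[i] * exp(-0.5 * ((t - centers[i]) / width_sd)^2)
  }
  v
}

# circadian amplitude envelope: raised cosine over 24 h peaking at the
# record start (sampling starts in the morning)
circadian_envelope <- function(t) 0.5 * (1 + cos(2 * pi * t / 1440))

# amplitude constants shared by the generators (ACTH in ng/l); chosen so a
# control profile reproduces healthy 12 h secretion totals and patient
# regimes the post-surgical fold increases
ACTH_BASELINE <- 8
ACTH_CONTROL_AMP <- 75

mult_noise <- function(v, frac) {
  if (frac <= 0) return(v)
  pmax(v * (1 + rnorm(length(v), 0, frac)), 0)
}

# observed ACTH: multiplicative assay noise plus a small additive floor so
# the between-pulse baseline fluctuates the way measured ACTH does; the
# cortisol model is driven by this observed trace, as in the real analysis
# where measured ACTH is the model input
acth_obs_noise <- function(v, frac) {
  if (frac <= 0) return(v)
  pmax(v * (1 + rnorm(length(v), 0, frac)) + rnorm(length(v), 0, 30 * frac), 0.5)
}

apply_extra_lag <- function(acth, spec, surgery_end) {
  # build the (possibly epoch-lagged) ACTH trace that drives the cortisol
  # model, emulating progressive loss of peak association
  if (spec$cortisol_lag == 0 && spec$synchrony_mode == "stable") return(acth)
  v <- acth$v
  shift_at <- function(tt, lag) approx(acth$t, acth$v, xout = tt - lag, rule = 2)$y
  if (spec$synchrony_mode == "partial") {
    # dissociation develops during surgery and persists
    onset <- surgery_end - 90
    out <- ifelse(acth$t < onset, v, shift_at(acth$t, spec$cortisol_lag))
  } else if (spec$synchrony_mode == "unstable") {
    # smoothly wandering lag: a fresh magnitude per 2 h epoch, interpolated
    # between epochs; the warp slope stays below 1 so the excursion is
    # displaced, never fragmented
    n_ep <- ceiling(max(acth$t) / 120) + 1
    ep_lag <- runif(n_ep, 0.4, 1.6) * spec$cortisol_lag
    lag_t <- approx(seq(0, by = 120, length.out = n_ep), ep_lag,
                    xout = acth$t, rule = 2)$y
    out <- shift_at(acth$t, lag_t)
  } else {
    out <- shift_at(acth$t, spec$cortisol_lag)
  }
  hpa_ts(out, t = acth$t, units = acth$units, name = acth$name)
}

regime_model_params <- function(regime) {
  cp <- control_params()
  switch(regime,
    control = cp,
    # two-pulse: control-like but slower cortisol clearance (larger lambda_s)
    two_pulse = model_params(cp$p_f, 1, cp$lambda_f, 300, cp$K_A, cp$m, cp$delay),
    # multiple-pulse: increased adrenal sensitivity (lower K_A)
    multiple_pulse = model_params(cp$p_f, 0.8, cp$lambda_f, cp$lambda_s,
                                  35, cp$m, cp$delay),
    # single-pulse: higher slow production, faster slow turnover
    single_pulse = model_params(cp$p_f, 3, cp$lambda_f, 80, cp$K_A, cp$m, cp$delay))
}

#' Generate a healthy-control profile
#'
#' ACTH as a train of Gaussian pulses with inter-pulse intervals drawn in
#' 150–180 min and amplitude modulated by a 24 h raised-cosine envelope
#' peaking at the record start (morning); cortisol generated from the ACTH
#' trace by the two-compartment model with control-calibrated parameters;
#' multiplicative measurement noise on both reported series.
#'
#' @param spec a control [regime_spec()] (duration at least 12 h).
#' @param seed integer seed.
#' @return A [subject_profile()] with `true_regime = "control"`.
#' @export
gen_healthy_profile <- function(spec = regime_spec("control"), seed = 1L) {
  stopifnot(inherits(spec, "regime_spec"))
  if (spec$regime != "control") hpa_stop("spec must have regime = 'control'", "value_error")
  if (spec$duration < 720) hpa_stop("duration must be at least 12 h", "value_error")
  with_seed(seed, {
    t <- seq(0, spec$duration, by = 10)
    centers <- 40 + cumsum(c(0, runif(ceiling(spec$duration / 150), 150, 180)))
    centers <- centers[centers < spec$duration]
    amps <- ACTH_CONTROL_AMP * spec$acth_peak_scale *
      circadian_envelope(centers) * runif(length(centers), 0.85, 1.15)
    acth_true <- pulse_train(t, centers, amps, width_sd = 15, baseline = ACTH_BASELINE)
    acth <- hpa_ts(acth_obs_noise(acth_true, spec$noise_sd_frac), t = t,
                   units = "ng/l", name = "ACTH")
    params <- regime_model_params("control")
    c0 <- steady_state_cortisol(params, acth$v[1])
    sim <- simulate_cortisol(params, acth, c_obs0 = c0)
    cort <- hpa_ts(mult_noise(sim$C, spec$noise_sd_frac), t = t,
                   units = "nmol/l", name = "cortisol")
    subject_profile(sprintf("control_s%d", seed), acth, cort,
                    true_regime = "control")
  })
}

#' Generate a post-surgical (disrupted) profile
#'
#' ACTH trace per regime — two large pulses at 300–360 min spacing, pulses
#' every ~2 h with jittered intervals, or one large excursion peaking ~2 h
#' after the end of surgery — with cortisol generated from the ACTH trace by
#' the model under regime-specific parameters. For the dissociated regimes an
#' extra ACTH-to-cortisol lag is applied (from surgery end for partial
#' synchrony; per 2 h epoch with random sign for unstable synchrony).
#'
#' @param spec a [regime_spec()] with a non-control regime.
#' @param seed integer seed.
#' @param surgery_window surgery span in minutes (default 55–230, matching a
#'   morning operation of about 3 h starting shortly after first
#'   cannulation).
#' @return A [subject_profile()] with `surgery_window` and `true_regime` set.
#' @export
gen_cabg_profile <- function(spec, seed = 1L, surgery_window = c(55, 230)) {
  stopifnot(inherits(spec, "regime_spec"))
  if (spec$regime == "control") {
    hpa_stop("use gen_healthy_profile() for the control regime", "value_error")
  }
  with_seed(seed, {
    t <- seq(0, spec$duration, by = 10)
    amp0 <- ACTH_CONTROL_AMP * spec$acth_peak_scale
    if (spec$regime == "two_pulse") {
      spacing <- runif(1, 300, 360)
      centers <- c(surgery_window[2] - 60, surgery_window[2] - 60 + spacing)
      acth_true <- pulse_train(t, centers, amp0 * runif(2, 0.85, 1.15),
                               width_sd = 17, baseline = ACTH_BASELINE)
    } else if (spec$regime == "multiple_pulse") {
      gaps <- runif(ceiling(spec$duration / 100) + 1, 0.85, 1.15) * spec$pulse_period
      centers <- surgery_window[1] + 30 + cumsum(c(0, gaps))
      centers <- centers[centers < spec$duration - 20]
      acth_true <- pulse_train(t, centers, amp0 * runif(length(centers), 0.8, 1.2),
                               width_sd = 8, baseline = ACTH_BASELINE)
    } else {  # single_pulse: maximum ~2 h after the end of surgery
      centre <- surgery_window[2] + 120
      acth_true <- pulse_train(t, centre, amp0, width_sd = 35,
                               baseline = ACTH_BASELINE)
    }
    acth <- hpa_ts(acth_obs_noise(acth_true, spec$noise_sd_frac), t = t,
                   units = "ng/l", name = "ACTH")
    drive_input <- apply_extra_lag(acth, spec, surgery_window[2])
    params <- regime_model_params(spec$regime)
    c0 <- steady_state_cortisol(params, drive_input$v[1])
    sim <- simulate_cortisol(params, drive_input, c_obs0 = c0)
    cort <- hpa_ts(mult_noise(sim$C, spec$noise_sd_frac), t = t,
                   units = "nmol/l", name = "cortisol")
    subject_profile(sprintf("%s_s%d", spec$regime, seed), acth, cort,
                    surgery_window = surgery_window, true_regime = spec$regime)
  })
}

# mediator-specific response timing (peak, minutes after the surgery
# midpoint), spread and typical peak level (pg/ml); responses are smooth
# rise-and-decay humps that clear before/near the record end
CYTOKINE_SHAPE <- list(
  IL6  = list(peak_t = 430, width = 75, gain = 250),
  TNFa = list(peak_t = 150, width = 55, gain = 30),
  IL10 = list(peak_t = 150, width = 60, gain = 120),
  IL8  = list(peak_t = 240, width = 90, gain = 60)
)

#' Add synthetic cytokine responses to a profile
#'
#' Adds IL6, TNFa, IL10 and IL8 series: a near-zero baseline before the
#' midpoint of the surgery window, then a smooth rise-and-decay response with
#' mediator-specific peak time and gain (inflammatory responses typically
#' begin during the second half of surgery). A mediator listed in `coupling`
#' additionally injects a cortisol disturbance proportional to its own trace,
#' used by the residual-correlation analysis to plant a known
#' inflammation-cortisol coupling.
#'
#' @param profile a [subject_profile()] with a surgery window.
#' @param coupling named list mediator -> gain (nmol/l of cortisol per pg/ml
#'   of mediator); empty for no coupling.
#' @param seed integer seed.
#' @param gains optional named overrides of the mediator peak levels (pg/ml);
#'   a gain of 0 yields a flat baseline trace.
#' @return The profile with cytokine series added (and cortisol perturbed if
#'   coupled).
#' @export
gen_cytokine_traces <- function(profile, coupling = list(), seed = 1L,
                                gains = NULL) {
  stopifnot(inherits(profile, "subject_profile"))
  if (is.null(profile$surgery_window)) {
    hpa_stop("profile has no surgery_window", "state_error")
  }
  onset <- mean(profile$surgery_window)
  t <- profile$acth$t
  with_seed(seed, {
    cyt <- list()
    disturbance <- 0
    for (nm in names(CYTOKINE_SHAPE)) {
      sh <- CYTOKINE_SHAPE[[nm]]
      g <- if (!is.null(gains) && nm %in% names(gains)) gains[[nm]] else sh$gain
      shape <- exp(-0.5 * ((t - onset - sh$peak_t) / sh$width)^2) * (t > onset)
      v <- 0.5 + g * shape * runif(1, 0.85, 1.15)
      v <- pmax(v + rnorm(length(v), 0, 0.01 * max(g, 1)), 0)
      cyt[[nm]] <- hpa_ts(v, t = t, units = "pg/ml", name = nm)
      if (nm %in% names(coupling)) {
        disturbance <- disturbance + coupling[[nm]] * cyt[[nm]]$v
      }
    }
    cort <- profile$cortisol
    if (!identical(disturbance, 0)) {
      cort <- hpa_ts(pmax(cort$v + disturbance, 0), t = t, units = "nmol/l",
                     name = "cortisol")
    }
    subject_profile(profile$subject_id, profile$acth, cort, cytokines = cyt,
                    surgery_window = profile$surgery_window,
                    true_regime = profile$true_regime)
  })
}

#' Model-generated cortisol with known ground-truth parameters
#'
#' Simulates the cortisol model for a given parameter set and ACTH input and
#' adds multiplicative Gaussian noise — the ground-truth generator for
#' parameter-recovery experiments.
#'
#' @param params [model_params()].
#' @param acth ACTH input series.
#' @param noise_sd_frac multiplicative noise SD (0 gives the exact model
#'   output).
#' @param seed integer seed.
#' @param c_obs0 initial observed cortisol; defaults to the steady state at
#'   the first ACTH sample.
#' @return An `hpa_ts` cortisol series; attribute `params` records the
#'   generating set.
#' @export
gen_model_cortisol <- function(params, acth, noise_sd_frac = 0, seed = 1L,
                               c_obs0 = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(acth, "hpa_ts"))
  c_obs0 <- c_obs0 %||% steady_state_cortisol(params, acth$v[1])
  sim <- simulate_cortisol(params, acth, c_obs0 = c_obs0)
  v <- with_seed(seed, mult_noise(sim$C, noise_sd_frac))
  out <- hpa_ts(v, t = acth$t, units = "nmol/l", name = "cortisol")
  attr(out, "params") <- params
  out
}

#' Generate a mixed synthetic panel
#'
#' One call producing a panel of profiles across regimes with
#' per-subject seeds derived from `seed`, optionally with cytokine traces
#' for the post-surgical subjects.
#'
#' @param n_per_regime subjects per regime.
#' @param regimes regimes to include.
#' @param seed master seed; subject `i` of regime `j` uses
#'   `seed + 1000*j + i`.
#' @param noise_sd_frac measurement-noise fraction for every subject.
#' @param cytokines add cytokine traces to post-surgical subjects?
#' @return A list of [subject_profile()] objects.
#' @export
gen_panel <- function(n_per_regime = 3,
                      regimes = c("control", "two_pulse", "multiple_pulse", "single_pulse"),
                      seed = 1L, noise_sd_frac = 0.05, cytokines = FALSE) {
  out <- list()
  for (j in seq_along(regimes)) {
    for (i in seq_len(n_per_regime)) {
      s <- seed + 1000L * j + i
      spec <- regime_spec(regimes[j], noise_sd_frac = noise_sd_frac)
      p <- if (regimes[j] == "control") gen_healthy_profile(spec, seed = s)
           else gen_cabg_profile(spec, seed = s)
      if (cytokines && regimes[j] != "control") {
        p <- gen_cytokine_traces(p, seed = s + 500L)
      }
      out[[length(out) + 1L]] <- p
    }
  }
  out
}
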