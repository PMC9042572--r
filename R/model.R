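#' Parameters of the open-loop two-compartment cortisol model
#'
#' Cortisol `C(t) = C_f(t) + C_s(t)` is modelled as two first-order
#' compartments, one fast and one slow, both driven by a delayed ACTH input
#' through a saturating Hill response:
#' \deqn{dC_f/dt = -C_f/\lambda_f + p_f H(A(t - delay))}
#' \deqn{dC_s/dt = -C_s/\lambda_s + p_s H(A(t - delay))}
#' with \eqn{H(A) = A^m / (K_A^m + A^m)}. The delay reflects the lag between
#' circulating ACTH and the adrenal secretory response (10 min by default).
#'
#' @param p_f,p_s fast and slow cortisol production rates (nmol/l per min).
#' @param lambda_f,lambda_s fast and slow time constants (min); their inverses
#'   are the turnover rates. Requires `lambda_f < lambda_s`.
#' @param K_A adrenal sensitivity: ACTH level (ng/l) giving half-maximal
#'   drive.
#' @param m Hill coefficient (steepness of the adrenal response), `>= 1`.
#' @param delay ACTH input delay in minutes.
#' @return An object of class `model_params`.
#' @export
model_params <- function(p_f, p_s, lambda_f, lambda_s, K_A, m = 2, delay = 10) {
  vals <- c(p_f = p_f, p_s = p_s, lambda_f = lambda_f, lambda_s = lambda_s,
            K_A = K_A, m = m, delay = delay)
  if (any(!is.finite(vals))) hpa_stop("all parameters must be finite", "value_error")
  if (p_f < 0 || p_s < 0) hpa_stop("production rates must be >= 0", "value_error")
  if (lambda_f <= 0 || lambda_s <= 0 || K_A <= 0) {
    hpa_stop("lambda_f, lambda_s and K_A must be > 0", "value_error")
  }
  if (lambda_f >= lambda_s) hpa_stop("lambda_f must be < lambda_s", "value_error")
  if (m < 1) hpa_stop("Hill coefficient m must be >= 1", "value_error")
  if (delay < 0) hpa_stop("delay must be >= 0", "value_error")
  structure(as.list(vals), class = "model_params")
}

#' Control-calibrated default model parameters
#'
#' Parameter set used to generate healthy-control cortisol from synthetic
#' ACTH: fast production dominating the pulsatile response (so model output
#' tracks ACTH at roughly the input delay), a slow compartment carrying the
#' baseline, adrenal sensitivity at the control median, and a Hill
#' coefficient of 2.
#' @return A [model_params()] object.
#' @export
control_params <- function() {
  model_params(p_f = 900, p_s = 0.5, lambda_f = 2, lambda_s = 180,
               K_A = 50.28, m = 2, delay = 10)
}

#' Hill-type adrenal drive
#'
#' Saturating response of adrenal cortisol production to ACTH:
#' `A^m / (K_A^m + A^m)`, in `[0, 1)`.
#'
#' @param A ACTH concentration(s), ng/l, `>= 0`.
#' @param K_A half-max sensitivity, ng/l.
#' @param m Hill coefficient.
#' @return Drive value(s) in `[0, 1)`.
#' @examples
#' hill_drive(50.28, K_A = 50.28, m = 2)  # half-max: 0.5
#' @export
hill_drive <- function(A, K_A, m) {
  if (any(A < 0)) hpa_stop("ACTH must be >= 0", "value_error")
  ifelse(A == 0, 0, A^m / (K_A^m + A^m))
}

# delayed, clamped ACTH input evaluated at absolute time t
delayed_acth <- function(acth, t, delay) {
  approx(acth$t, acth$v, xout = t - delay, rule = 2)$y
}

#' Initial compartment split
#'
#' The fast compartment starts at quasi-equilibrium with the (delayed,
#' clamped) ACTH drive at the record start; the slow compartment absorbs the
#' remainder of the observed initial cortisol, floored at zero.
#'
#' @param params [model_params()].
#' @param acth ACTH input series (ng/l), no missing values.
#' @param c_obs0 observed cortisol at the record start (nmol/l).
#' @return `c(C_f0, C_s0)`.
#' @export
initial_state <- function(params, acth, c_obs0) {
  stopifnot(inherits(params, "model_params"), inherits(acth, "hpa_ts"))
  if (c_obs0 < 0) hpa_stop("c_obs0 must be >= 0", "value_error")
  h0 <- hill_drive(delayed_acth(acth, acth$t[1], params$delay), params$K_A, params$m)
  cf0 <- params$p_f * params$lambda_f * h0
  c(C_f0 = cf0, C_s0 = max(c_obs0 - cf0, 0))
}

#' Simulate the two-compartment cortisol response to an ACTH record
#'
#' Integrates both compartments with a fixed-step classic 4th-order
#' Runge-Kutta scheme (step `<= 1` min, shrunk further for very fast
#' compartments), the ACTH input interpolated linearly between its samples
#' and clamped to the first sample before the record starts.
#'
#' @param params [model_params()].
#' @param acth ACTH input series (ng/l), no missing values.
#' @param t_out output time grid (minutes); defaults to the ACTH grid. Must
#'   lie within the ACTH record span.
#' @param c_obs0 observed initial cortisol (nmol/l) used to split the initial
#'   state; ignored when `state0` is given.
#' @param state0 optional explicit initial `c(C_f0, C_s0)` override.
#' @return A list of class `sim_result` with fields `t`, `C_f`, `C_s`,
#'   `C = C_f + C_s` and `params`.
#' @export
simulate_cortisol <- function(params, acth, t_out = NULL, c_obs0 = 0,
                              state0 = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(acth, "hpa_ts"))
  if (anyNA(acth$v)) hpa_stop("ACTH input contains missing values", "value_error")
  t_out <- t_out %||% acth$t
  if (t_out[1] < acth$t[1] - 1e-9 || t_out[length(t_out)] > acth$t[length(acth$t)] + 1e-9) {
    hpa_stop("t_out must lie within the ACTH record span", "range_error")
  }
  if (is.null(state0)) state0 <- initial_state(params, acth, c_obs0)
  m <- sim_rk4_cpp(acth$t, acth$v, params$delay, params$p_f, params$p_s,
                   params$lambda_f, params$lambda_s, params$K_A, params$m,
                   state0[1], state0[2], t_out)
  structure(list(t = t_out, C_f = m[, 1], C_s = m[, 2], C = m[, 1] + m[, 2],
                 params = params), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %d points over %g-%g min; C in [%.3g, %.3g] nmol/l\n",
              length(x$t), x$t[1], x$t[length(x$t)], min(x$C), max(x$C)))
  invisible(x)
}

#' Steady-state cortisol under a constant ACTH level
#'
#' Closed-form limit `(p_f lambda_f + p_s lambda_s) * H(A_const)` of the
#' model under a constant input; the simulated trajectory converges to this
#' value over a few slow time constants.
#'
#' @param params [model_params()].
#' @param A_const constant ACTH level, ng/l.
#' @return Steady-state cortisol, nmol/l.
#' @export
steady_state_cortisol <- function(params, A_const) {
  stopifnot(inherits(params, "model_params"))
  (params$p_f * params$lambda_f + params$p_s * params$lambda_s) *
    hill_drive(A_const, params$K_A, params$m)
}
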