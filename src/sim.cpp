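#include <Rcpp.h>
using namespace Rcpp;

// Piecewise-linear interpolation of the ACTH record at (t - delay), clamped
// to the first/last sample outside the record (no pre-record history is
// invented).
static inline double acth_at(const NumericVector& at, const NumericVector& av,
                             double t, double delay) {
  double x = t - delay;
  int n = at.size();
  if (x <= at[0]) return av[0];
  if (x >= at[n - 1]) return av[n - 1];
  // binary search for the bracketing interval
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (at[mid] <= x) lo = mid; else hi = mid;
  }
  double w = (x - at[lo]) / (at[hi] - at[lo]);
  return av[lo] + w * (av[hi] - av[lo]);
}

static inline double hill(double a, double ka, double m) {
  if (a <= 0.0) return 0.0;
  double am = std::pow(a, m), km = std::pow(ka, m);
  return am / (km + am);
}

// Classic explicit RK4 over [t0, t1] for the two uncoupled linear
// compartments driven by the Hill-transformed delayed ACTH input.
// Step size <= 1 min, shrunk further when lambda_f is small so that
// h / lambda stays <= 0.2.
static void integrate_span(const NumericVector& at, const NumericVector& av,
                           double delay, double pf, double ps,
                           double lf, double ls, double ka, double m,
                           double t0, double t1, double& cf, double& cs) {
  double h_max = std::min(1.0, lf / 5.0);
  int nstep = (int)std::ceil((t1 - t0) / h_max - 1e-12);
  if (nstep < 1) nstep = 1;
  double h = (t1 - t0) / nstep;
  double t = t0;
  for (int i = 0; i < nstep; ++i) {
    double u1 = hill(acth_at(at, av, t, delay), ka, m);
    double u2 = hill(acth_at(at, av, t + 0.5 * h, delay), ka, m);
    double u3 = hill(acth_at(at, av, t + h, delay), ka, m);
    // fast compartment
    double k1 = -cf / lf + pf * u1;
    double k2 = -(cf + 0.5 * h * k1) / lf + pf * u2;
    double k3 = -(cf + 0.5 * h * k2) / lf + pf * u2;
    double k4 = -(cf + h * k3) / lf + pf * u3;
    double cf_new = cf + h / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    // slow compartment
    double l1 = -cs / ls + ps * u1;
    double l2 = -(cs + 0.5 * h * l1) / ls + ps * u2;
    double l3 = -(cs + 0.5 * h * l2) / ls + ps * u2;
    double l4 = -(cs + h * l3) / ls + ps * u3;
    double cs_new = cs + h / 6.0 * (l1 + 2.0 * l2 + 2.0 * l3 + l4);
    cf = cf_new > 0.0 ? cf_new : 0.0;
    cs = cs_new > 0.0 ? cs_new : 0.0;
    t += h;
  }
}

// [[Rcpp::export]]
NumericMatrix sim_rk4_cpp(NumericVector acth_t, NumericVector acth_v,
                          double delay, double pf, double ps,
                          double lf, double ls, double ka, double m,
                          double cf0, double cs0, NumericVector t_out) {
  int n = t_out.size();
  NumericMatrix out(n, 2);
  double cf = cf0, cs = cs0;
  out(0, 0) = cf; out(0, 1) = cs;
  for (int i = 1; i < n; ++i) {
    integrate_span(acth_t, acth_v, delay, pf, ps, lf, ls, ka, m,
                   t_out[i - 1], t_out[i], cf, cs);
    out(i, 0) = cf; out(i, 1) = cs;
  }
  return out;
}

// Ensemble scorer: for each parameter row (pf, ps, lf, ls, ka, m) simulate
// on the observation grid and return the range-normalised RMSE against obs.
// [[Rcpp::export]]
NumericVector fit_eps_cpp(NumericVector acth_t, NumericVector acth_v,
                          double delay, NumericMatrix params,
                          double c_obs0, NumericVector t_out,
                          NumericVector obs) {
  int nset = params.nrow(), n = t_out.size();
  double omin = obs[0], omax = obs[0];
  for (int j = 1; j < n; ++j) {
    if (obs[j] < omin) omin = obs[j];
    if (obs[j] > omax) omax = obs[j];
  }
  double range = omax - omin;
  NumericVector eps(nset);
  for (int s = 0; s < nset; ++s) {
    double pf = params(s, 0), ps = params(s, 1), lf = params(s, 2),
           ls = params(s, 3), ka = params(s, 4), m = params(s, 5);
    double cf = pf * lf * hill(acth_at(acth_t, acth_v, t_out[0], delay), ka, m);
    double cs = c_obs0 - cf; if (cs < 0.0) cs = 0.0;
    double sse = (cf + cs - obs[0]) * (cf + cs - obs[0]);
    for (int i = 1; i < n; ++i) {
      integrate_span(acth_t, acth_v, delay, pf, ps, lf, ls, ka, m,
                     t_out[i - 1], t_out[i], cf, cs);
      double d = cf + cs - obs[i];
      sse += d * d;
    }
    double rmse = std::sqrt(sse / n);
    eps[s] = range > 0.0 ? rmse / range : R_PosInf;
  }
  return eps;
}
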