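#' Sampling ranges for the random-search calibration
#'
#' Per-parameter bounds and sampling scales for the ensemble random search,
#' plus fixed-value overrides used by the fixed-sensitivity and fixed-Hill
#' scenarios. Defaults span physiological cortisol half-lives and adrenal
#' sensitivities: production rates and time constants log-uniform, Hill
#' coefficient a uniform integer in 1..5, input delay fixed at 10 min.
#'
#' @param p_f,p_s,lambda_f,lambda_s,K_A `c(low, high)` bounds, sampled
#'   log-uniformly. The fast-production bound extends to 1000 nmol/l/min so
#'   that fast gains `p_f * lambda_f` of a few thousand remain reachable even
#'   for very fast compartments (`lambda_f` of a couple of minutes).
#' @param m integer bounds for the Hill coefficient, sampled uniformly.
#' @param fixed named list of fixed overrides (e.g. `list(K_A = 50.28)`); a
#'   fixed parameter is not sampled.
#' @param delay input delay in minutes (always fixed).
#' @return A list of class `param_ranges`.
#' @export
param_ranges <- function(p_f = c(1e-2, 1e3), p_s = c(1e-2, 1e2),
                         lambda_f = c(1, 60), lambda_s = c(30, 600),
                         K_A = c(1, 500), m = c(1, 5),
                         fixed = list(), delay = 10) {
  bounds <- list(p_f = p_f, p_s = p_s, lambda_f = lambda_f,
                 lambda_s = lambda_s, K_A = K_A, m = m)
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (length(b) != 2 || !(b[1] < b[2]) || b[1] <= 0) {
      hpa_stop(sprintf("invalid bounds for %s", nm), "value_error")
    }
  }
  for (nm in names(fixed)) {
    if (!nm %in% names(bounds)) hpa_stop(sprintf("unknown fixed parameter %s", nm), "value_error")
  }
  structure(list(bounds = bounds, fixed = fixed, delay = delay),
            class = "param_ranges")
}

#' Apply a calibration scenario to sampling ranges
#'
#' `fixed_KA` pins the adrenal sensitivity at the control-median value
#' 50.28; `fixed_m` pins the Hill coefficient at 2; `fixed_both` does both;
#' `free_KA` leaves the ranges untouched.
#'
#' @param ranges a [param_ranges()].
#' @param scenario scenario name.
#' @return The modified `param_ranges`.
#' @export
apply_scenario <- function(ranges,
                           scenario = c("free_KA", "fixed_KA", "fixed_m", "fixed_both")) {
  scenario <- match.arg(scenario)
  if (scenario %in% c("fixed_KA", "fixed_both")) ranges$fixed$K_A <- 50.28
  if (scenario %in% c("fixed_m", "fixed_both")) ranges$fixed$m <- 2
  ranges
}

#' Draw random parameter sets
#'
#' Independent draws per parameter on the stated scale (log-uniform for
#' rates/time constants/sensitivity, uniform integer for the Hill
#' coefficient); fixed overrides are applied verbatim. Draws violating
#' `lambda_f < lambda_s` are rejected and redrawn, so every returned set is a
#' valid parameter vector. Fully reproducible under `seed`.
#'
#' @param ranges a [param_ranges()].
#' @param n number of sets, `>= 1`.
#' @param seed integer seed.
#' @return A data frame with columns `p_f, p_s, lambda_f, lambda_s, K_A, m,
#'   delay`, one row per set.
#' @export
sample_parameter_sets <- function(ranges, n, seed) {
  stopifnot(inherits(ranges, "param_ranges"))
  if (!is_scalar_number(n) || n < 1) hpa_stop("n must be >= 1", "value_error")
  n <- as.integer(n)
  draw <- function(nm, k) {
    if (nm %in% names(ranges$fixed)) return(rep(ranges$fixed[[nm]], k))
    b <- ranges$bounds[[nm]]
    if (nm == "m") {
      sample(seq(b[1], b[2]), k, replace = TRUE)
    } else {
      exp(runif(k, log(b[1]), log(b[2])))
    }
  }
  with_seed(seed, {
    df <- data.frame(p_f = draw("p_f", n), p_s = draw("p_s", n),
                     lambda_f = draw("lambda_f", n), lambda_s = draw("lambda_s", n),
                     K_A = draw("K_A", n), m = draw("m", n), delay = ranges$delay)
    bad <- which(df$lambda_f >= df$lambda_s)
    guard <- 0L
    while (length(bad) && guard < 1000L) {
      df$lambda_f[bad] <- draw("lambda_f", length(bad))
      df$lambda_s[bad] <- draw("lambda_s", length(bad))
      bad <- bad[df$lambda_f[bad] >= df$lambda_s[bad]]
      guard <- guard + 1L
    }
    if (length(bad)) hpa_stop("cannot satisfy lambda_f < lambda_s within the given bounds", "value_error")
    df
  })
}

#' Range-normalised fit error
#'
#' `epsilon = RMSE(pred, obs) / (max(obs) - min(obs))`: dimensionless,
#' offset-sensitive, and comparable across subjects with different cortisol
#' dynamic ranges. Returns `Inf` when the observed trace is constant.
#'
#' @param pred,obs predicted and observed series (`hpa_ts` on one grid, or
#'   plain numeric vectors of equal length).
#' @return Non-negative `epsilon`.
#' @export
fit_error <- function(pred, obs) {
  if (inherits(pred, "hpa_ts") && inherits(obs, "hpa_ts")) {
    ts_check_shared_grid(pred, obs)
    pred <- pred$v; obs <- obs$v
  }
  if (length(pred) != length(obs)) hpa_stop("pred and obs must share a grid", "value_error")
  rng <- max(obs) - min(obs)
  if (rng == 0) return(Inf)
  sqrt(mean((pred - obs)^2)) / rng
}

#' Ensemble random-search calibration of the cortisol model
#'
#' Scores `n` random parameter sets by simulating the model with the
#' subject's ACTH as input and comparing against the observed cortisol with
#' [fit_error()], keeping the `keep` best. The result is an ensemble of good
#' fits (not a single optimum), from which parameter distributions are
#' summarised.
#'
#' @param profile a [subject_profile()] with ACTH and cortisol on one grid
#'   and no missing values.
#' @param ranges a [param_ranges()]; the scenario's fixed overrides are
#'   applied on top.
#' @param n number of random draws.
#' @param keep number of best sets to retain (`<= n`); default `n / 1000`.
#' @param seed integer seed.
#' @param scenario calibration scenario, see [apply_scenario()].
#' @return A list of class `fit_ensemble`: `results` (data frame of kept
#'   parameter sets with `epsilon`, ascending), `n_sampled`,
#'   `selection_rule`, `seed`, `scenario`.
#' @export
fit_ensemble <- function(profile, ranges = param_ranges(), n = 1e5,
                         keep = NULL, seed = 1L,
                         scenario = c("free_KA", "fixed_KA", "fixed_m", "fixed_both")) {
  stopifnot(inherits(profile, "subject_profile"))
  scenario <- match.arg(scenario)
  keep <- keep %||% max(1L, round(n / 1000))
  if (n < keep) hpa_stop("n must be >= keep", "value_error")
  a <- profile$acth; obs <- profile$cortisol
  if (anyNA(a$v) || anyNA(obs$v)) hpa_stop("fitting requires complete series", "value_error")
  ranges <- apply_scenario(ranges, scenario)
  draws <- sample_parameter_sets(ranges, n, seed)
  eps <- fit_eps_cpp(a$t, a$v, ranges$delay,
                     as.matrix(draws[, c("p_f", "p_s", "lambda_f", "lambda_s", "K_A", "m")]),
                     obs$v[1], obs$t, obs$v)
  ord <- order(eps)[seq_len(keep)]
  res <- draws[ord, , drop = FALSE]
  res$epsilon <- eps[ord]
  rownames(res) <- NULL
  structure(list(results = res, n_sampled = n,
                 selection_rule = sprintf("lowest-epsilon %d of %d random draws", keep, n),
                 seed = seed, scenario = scenario),
            class = "fit_ensemble")
}

#' @export
print.fit_ensemble <- function(x, ...) {
  cat(sprintf("<fit_ensemble> %s: kept %d of %d draws; epsilon range %.4f-%.4f\n",
              x$scenario, nrow(x$results), x$n_sampled,
              min(x$results$epsilon), max(x$results$epsilon)))
  invisible(x)
}

#' Best-fitting parameter set of an ensemble
#' @param e a [fit_ensemble()].
#' @return A [model_params()] built from the lowest-epsilon kept set.
#' @export
best_fit_params <- function(e) {
  stopifnot(inherits(e, "fit_ensemble"))
  b <- e$results[1, ]
  model_params(b$p_f, b$p_s, b$lambda_f, b$lambda_s, b$K_A, b$m, b$delay)
}

#' Summarise the parameter distributions of a fit ensemble
#'
#' Per-parameter quantiles (min, 5%, 25%, 50%, 75%, 95%, max) plus a kernel
#' density estimate per parameter on a 128-point grid — the tabular
#' counterpart of the violin plots used to compare scenarios and groups.
#'
#' @param e a [fit_ensemble()] with at least one kept set.
#' @return A list of class `ensemble_summary` with `quantiles` (data frame)
#'   and `density` (named list of `x`/`y` grids).
#' @export
summarize_ensemble <- function(e) {
  stopifnot(inherits(e, "fit_ensemble"))
  if (!nrow(e$results)) hpa_stop("empty ensemble", "state_error")
  pars <- c("p_f", "p_s", "lambda_f", "lambda_s", "K_A", "m", "epsilon")
  probs <- c(0, 0.05, 0.25, 0.5, 0.75, 0.95, 1)
  q <- t(vapply(pars, function(p) quantile(e$results[[p]], probs, names = FALSE),
                numeric(length(probs))))
  colnames(q) <- c("min", "q05", "q25", "median", "q75", "q95", "max")
  dens <- lapply(pars, function(p) {
    x <- e$results[[p]]
    if (length(unique(x)) < 2) return(list(x = unique(x), y = 1))
    d <- stats::density(x, n = 128)
    list(x = d$x, y = d$y)
  })
  names(dens) <- pars
  structure(list(quantiles = data.frame(parameter = pars, q, row.names = NULL),
                 density = dens, scenario = e$scenario),
            class = "ensemble_summary")
}

#' Compare parameter distributions between two ensembles
#'
#' Pairwise scenario comparison: shift in the median and ratio of
#' inter-quartile ranges, per parameter.
#'
#' @param e1,e2 two [fit_ensemble()] objects (e.g. different scenarios or
#'   subject groups).
#' @return A data frame with `parameter`, `median_shift` (e2 - e1) and
#'   `iqr_ratio` (e2 / e1).
#' @export
compare_ensembles <- function(e1, e2) {
  stopifnot(inherits(e1, "fit_ensemble"), inherits(e2, "fit_ensemble"))
  pars <- c("p_f", "p_s", "lambda_f", "lambda_s", "K_A", "m")
  do.call(rbind, lapply(pars, function(p) {
    x1 <- e1$results[[p]]; x2 <- e2$results[[p]]
    i1 <- diff(quantile(x1, c(0.25, 0.75), names = FALSE))
    i2 <- diff(quantile(x2, c(0.25, 0.75), names = FALSE))
    data.frame(parameter = p, median_shift = median(x2) - median(x1),
               iqr_ratio = if (i1 > 0) i2 / i1 else NA_real_)
  }))
}
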