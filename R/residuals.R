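#' Time-varying model residual
#'
#' Observed cortisol minus model prediction, elementwise on a shared grid.
#'
#' @param pred predicted cortisol (`hpa_ts`).
#' @param obs observed cortisol (`hpa_ts`).
#' @return An `hpa_ts` residual in nmol/l (stored dimensionless so negative
#'   values are representable).
#' @export
residual_series <- function(pred, obs) {
  stopifnot(inherits(pred, "hpa_ts"), inherits(obs, "hpa_ts"))
  ts_check_shared_grid(pred, obs)
  hpa_ts(obs$v - pred$v, t = obs$t, units = "dimensionless", name = "residual")
}

#' Z-score normalisation
#'
#' `(v - mean) / sd` using the sample (n-1) standard deviation; the output
#' has mean 0 and sd 1 exactly.
#'
#' @param ts an `hpa_ts` with at least two distinct values (missing samples
#'   are ignored in the moments and propagated).
#' @return A dimensionless `hpa_ts`.
#' @export
zscore_normalize <- function(ts) {
  stopifnot(inherits(ts, "hpa_ts"))
  s <- sd(ts$v, na.rm = TRUE)
  if (is.na(s) || s == 0) hpa_stop("constant series cannot be z-scored", "value_error")
  hpa_ts((ts$v - mean(ts$v, na.rm = TRUE)) / s, t = ts$t,
         units = "dimensionless", name = paste0("z(", ts$name, ")"))
}

#' Principal component analysis of cytokine trajectories
#'
#' Pools post-surgery-onset time points across subjects (observations) with
#' one z-scored variable per mediator, and reports component loadings,
#' variance explained and which mediators dominate the first component. Used
#' to pick the mediators carried into the residual-correlation analysis.
#'
#' @param panel list of [subject_profile()] with cytokines and surgery
#'   windows.
#' @param mediators mediator names to include.
#' @return A list of class `cytokine_pca`: `loadings` (mediators x
#'   components), `variance_explained`, `dominant` (mediators ordered by
#'   |loading| on PC1).
#' @export
cytokine_pca <- function(panel, mediators = c("IL6", "TNFa", "IL10", "IL8")) {
  if (inherits(panel, "subject_profile")) panel <- list(panel)
  cols <- lapply(mediators, function(nm) {
    unlist(lapply(panel, function(p) {
      if (!nm %in% names(p$cytokines)) return(numeric(0))
      keep <- if (is.null(p$surgery_window)) TRUE else p$cytokines[[nm]]$t >= p$surgery_window[1]
      p$cytokines[[nm]]$v[keep]
    }))
  })
  names(cols) <- mediators
  len <- unique(lengths(cols))
  if (length(len) != 1 || len[1] < 3) {
    hpa_stop("mediators must be present with equal pooled lengths", "value_error")
  }
  for (nm in mediators) {
    x <- cols[[nm]]
    if (mean(is.na(x)) > 0.5 || sd(x, na.rm = TRUE) %in% c(0, NA)) {
      hpa_stop(sprintf("mediator %s is missing or constant", nm), "value_error")
    }
    cols[[nm]] <- (x - mean(x, na.rm = TRUE)) / sd(x, na.rm = TRUE)
  }
  X <- do.call(cbind, cols)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = pc$rotation, variance_explained = ve,
                 dominant = mediators[order(-abs(pc$rotation[, 1]))]),
            class = "cytokine_pca")
}

DEFAULT_COMBOS <- list("IL6", "TNFa", "IL8", "IL10",
                       c("IL6", "TNFa"), c("IL6", "TNFa", "IL8"),
                       c("IL6", "TNFa", "IL10"), c("IL6", "TNFa", "IL8", "IL10"))

combo_label <- function(combo) paste(combo, collapse = "+")

# additive combination: sum of individually z-scored members, re-z-scored
combo_trace <- function(profile, combo) {
  if (!all(combo %in% names(profile$cytokines))) return(NULL)
  zs <- lapply(profile$cytokines[combo], zscore_normalize)
  v <- Reduce(`+`, lapply(zs, function(z) z$v))
  out <- hpa_ts(v, t = zs[[1]]$t, units = "dimensionless", name = combo_label(combo))
  if (length(combo) > 1) out <- zscore_normalize(out)
  out
}

#' Residual-versus-mediator correlation matrix
#'
#' For each subject, the Pearson correlation between the z-scored model
#' residual and each z-scored mediator (or additive combination of z-scored
#' mediators). One row per subject, one column per combination; a combination
#' referencing a mediator absent from a subject gives a missing cell.
#'
#' @param residuals named list (by subject id) of residual `hpa_ts`.
#' @param panel list of [subject_profile()] providing the cytokine series,
#'   in the same order.
#' @param combos list of mediator combinations.
#' @return A list of class `residual_report`: `correlations` (subjects x
#'   combos matrix), `combos`, `residuals`.
#' @export
residual_cytokine_correlations <- function(residuals, panel,
                                           combos = DEFAULT_COMBOS) {
  if (inherits(panel, "subject_profile")) panel <- list(panel)
  stopifnot(length(residuals) == length(panel))
  labels <- vapply(combos, combo_label, character(1))
  m <- matrix(NA_real_, nrow = length(panel), ncol = length(combos),
              dimnames = list(vapply(panel, `[[`, character(1), "subject_id"), labels))
  for (i in seq_along(panel)) {
    r <- residuals[[i]]
    ts_check_shared_grid(r, panel[[i]]$acth)
    zr <- zscore_normalize(r)
    for (j in seq_along(combos)) {
      ct <- combo_trace(panel[[i]], combos[[j]])
      if (is.null(ct)) next
      m[i, j] <- cor(zr$v, ct$v, use = "complete.obs")
    }
  }
  structure(list(correlations = m, combos = combos, residuals = residuals),
            class = "residual_report")
}

#' Model residuals for a panel under the fixed-sensitivity scenario
#'
#' Fits the model to each subject (fixed `K_A = 50.28`, fixed `m = 2` by
#' default, matching the configuration used for residual analysis) and
#' returns each subject's residual against the best-fit prediction.
#'
#' @param panel list of [subject_profile()].
#' @param n_draws,keep random-search budget per subject.
#' @param seed master seed (per-subject seeds derived from it).
#' @param scenario calibration scenario; default `fixed_both`.
#' @return Named list of residual `hpa_ts`, one per subject.
#' @export
panel_residuals <- function(panel, n_draws = 5000, keep = 10, seed = 1L,
                            scenario = "fixed_both") {
  if (inherits(panel, "subject_profile")) panel <- list(panel)
  res <- lapply(seq_along(panel), function(i) {
    p <- panel[[i]]
    ens <- fit_ensemble(p, n = n_draws, keep = keep, seed = seed + i,
                        scenario = scenario)
    best <- best_fit_params(ens)
    sim <- simulate_cortisol(best, p$acth, t_out = p$cortisol$t,
                             c_obs0 = p$cortisol$v[1])
    pred <- hpa_ts(sim$C, t = p$cortisol$t, units = "nmol/l", name = "pred")
    residual_series(pred, p$cortisol)
  })
  names(res) <- vapply(panel, `[[`, character(1), "subject_id")
  res
}
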