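#' Run the full analysis pipeline on a panel
#'
#' Sequences the stages — synchrony battery, phenotype classification,
#' ensemble model calibration, and residual-versus-cytokine correlation —
#' over a panel of subject profiles, fully deterministically given the seeds
#' in the configuration.
#'
#' @param panel list of [subject_profile()] (e.g. from [gen_panel()] or
#'   [read_panel_csv()]).
#' @param config an [analysis_config()]; `n_draws`, `keep`, `scenario` and
#'   `seed` control the calibration stage.
#' @param out_dir optional directory; when given, per-stage CSV tables and a
#'   JSON manifest are written there.
#' @return A list of class `pipeline_report`: `phenotypes` (data frame),
#'   `fits` (named list of [fit_ensemble()]), `fit_summaries`,
#'   `residual_report` (or `NULL` when no subject has cytokines),
#'   `manifest`.
#' @export
run_pipeline <- function(panel, config = analysis_config(), out_dir = NULL) {
  if (inherits(panel, "subject_profile")) panel <- list(panel)
  if (!length(panel)) hpa_stop("panel is empty", "value_error")
  ids <- vapply(panel, `[[`, character(1), "subject_id")

  metrics <- lapply(panel, compute_sync_metrics, config = config)
  calls <- lapply(metrics, classify_profile, config = config)
  phenotypes <- data.frame(
    subject_id = ids,
    label = vapply(calls, `[[`, character(1), "label"),
    true_regime = vapply(panel, function(p) p$true_regime %||% NA_character_, character(1)),
    n_pulses = vapply(metrics, `[[`, numeric(1), "n_pulses"),
    period_min = vapply(metrics, `[[`, numeric(1), "period"),
    peak_lag_min = vapply(metrics, `[[`, numeric(1), "peak_lag"),
    stability = vapply(metrics, `[[`, numeric(1), "stability"),
    rule_trace = vapply(calls, function(x) x$rule_trace[1], character(1)),
    stringsAsFactors = FALSE)

  fits <- lapply(seq_along(panel), function(i) {
    fit_ensemble(panel[[i]], n = config$n_draws, keep = config$keep,
                 seed = config$seed + i, scenario = config$scenario)
  })
  names(fits) <- ids
  fit_summaries <- lapply(fits, summarize_ensemble)

  with_cyt <- vapply(panel, function(p) length(p$cytokines) > 0, logical(1))
  residual_report <- NULL
  if (any(with_cyt)) {
    sub <- panel[with_cyt]
    res <- lapply(which(with_cyt), function(i) {
      p <- panel[[i]]
      best <- best_fit_params(fits[[i]])
      sim <- simulate_cortisol(best, p$acth, t_out = p$cortisol$t,
                               c_obs0 = p$cortisol$v[1])
      residual_series(hpa_ts(sim$C, t = p$cortisol$t, units = "nmol/l"), p$cortisol)
    })
    names(res) <- ids[with_cyt]
    residual_report <- residual_cytokine_correlations(res, sub)
  }

  manifest <- list(n_subjects = length(panel), subject_ids = ids,
                   scenario = config$scenario, n_draws = config$n_draws,
                   keep = config$keep, seed = config$seed,
                   skipped_residuals = ids[!with_cyt])
  report <- structure(list(phenotypes = phenotypes, fits = fits,
                           fit_summaries = fit_summaries,
                           residual_report = residual_report,
                           manifest = manifest),
                      class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_report(report, out_dir)
  report
}

write_pipeline_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$phenotypes, file.path(out_dir, "phenotypes.csv"), row.names = FALSE)
  fits_tab <- do.call(rbind, lapply(names(report$fits), function(id) {
    cbind(subject_id = id, report$fits[[id]]$results)
  }))
  write.csv(fits_tab, file.path(out_dir, "fit_ensembles.csv"), row.names = FALSE)
  if (!is.null(report$residual_report)) {
    m <- report$residual_report$correlations
    write.csv(data.frame(subject_id = rownames(m), m, check.names = FALSE),
              file.path(out_dir, "residual_correlations.csv"), row.names = FALSE)
  }
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d subjects; labels: %s\n",
              x$manifest$n_subjects,
              paste(sprintf("%s=%d", names(table(x$phenotypes$label)),
                            as.integer(table(x$phenotypes$label))), collapse = ", ")))
  invisible(x)
}
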