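CYTOKINE_NAMES <- c("IL6", "TNFa", "IL10", "IL8", "IL2", "IL4", "IL1a")

#' Per-subject hormone and cytokine profile
#'
#' Bundles a subject's ACTH and cortisol series with any inflammatory-mediator
#' series, all on one shared time grid, plus the surgery window and (for
#' synthetic subjects) the true generating regime.
#'
#' @param subject_id subject label.
#' @param acth ACTH [hpa_ts()] in ng/l.
#' @param cortisol cortisol [hpa_ts()] in nmol/l.
#' @param cytokines named list of `hpa_ts` in pg/ml; names drawn from
#'   IL6, TNFa, IL10, IL8, IL2, IL4, IL1a.
#' @param surgery_window optional `c(start_min, end_min)`.
#' @param true_regime optional generating-regime label (synthetic data only).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, acth, cortisol, cytokines = list(),
                            surgery_window = NULL, true_regime = NULL) {
  stopifnot(inherits(acth, "hpa_ts"), inherits(cortisol, "hpa_ts"))
  ts_check_shared_grid(acth, cortisol)
  if (length(cytokines)) {
    nm <- names(cytokines)
    if (is.null(nm) || any(!nm %in% CYTOKINE_NAMES)) {
      hpa_stop(paste("cytokine names must be among:", paste(CYTOKINE_NAMES, collapse = ", ")),
               "value_error")
    }
    for (cy in cytokines) {
      stopifnot(inherits(cy, "hpa_ts"))
      ts_check_shared_grid(acth, cy)
    }
  }
  if (!is.null(surgery_window)) {
    stopifnot(length(surgery_window) == 2, surgery_window[1] < surgery_window[2])
  }
  structure(list(subject_id = as.character(subject_id), acth = acth,
                 cortisol = cortisol, cytokines = cytokines,
                 surgery_window = surgery_window, true_regime = true_regime),
            class = "subject_profile")
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf("<subject_profile> %s: %d samples at dt = %g min; cytokines: %s%s%s\n",
              x$subject_id, length(x$acth$v), x$acth$dt,
              if (length(x$cytokines)) paste(names(x$cytokines), collapse = ",") else "none",
              if (!is.null(x$surgery_window))
                sprintf("; surgery %g-%g min", x$surgery_window[1], x$surgery_window[2]) else "",
              if (!is.null(x$true_regime)) paste0("; regime ", x$true_regime) else ""))
  invisible(x)
}

analyte_units <- function(analyte) {
  if (analyte == "ACTH") "ng/l"
  else if (analyte == "cortisol") "nmol/l"
  else if (analyte %in% CYTOKINE_NAMES) "pg/ml"
  else "dimensionless"
}

#' Write a panel of subject profiles as canonical long-format CSV
#'
#' Canonical columns: `subject_id, analyte, t_min, value, units`, plus the
#' metadata columns `surgery_start, surgery_end, true_regime` (repeated per
#' row, empty when absent). Missing samples are written as empty cells.
#'
#' @param panel a `subject_profile` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(panel, path) {
  if (inherits(panel, "subject_profile")) panel <- list(panel)
  rows <- lapply(panel, function(p) {
    series <- c(list(ACTH = p$acth, cortisol = p$cortisol), p$cytokines)
    do.call(rbind, lapply(names(series), function(an) {
      s <- series[[an]]
      data.frame(subject_id = p$subject_id, analyte = an, t_min = s$t,
                 value = signif(s$v, 9), units = s$units,
                 surgery_start = if (is.null(p$surgery_window)) NA_real_ else p$surgery_window[1],
                 surgery_end = if (is.null(p$surgery_window)) NA_real_ else p$surgery_window[2],
                 true_regime = p$true_regime %||% NA_character_,
                 stringsAsFactors = FALSE)
    }))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a panel of subject profiles from CSV
#'
#' Reads the canonical long format written by [write_panel_csv()], or a wide
#' format (one subject per file: a time column plus one column per analyte).
#' Column names can be remapped through `schema`.
#'
#' @param path CSV path.
#' @param format `"long"` (canonical) or `"wide"`.
#' @param schema optional named list remapping the expected column names; for
#'   long format the keys are `subject_id, analyte, t_min, value, units`, for
#'   wide format the key `t_min` plus `subject_id` (a constant label).
#' @return A list of [subject_profile()] objects.
#' @export
read_panel_csv <- function(path, format = c("long", "wide"), schema = NULL) {
  format <- match.arg(format)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (format == "wide") return(read_panel_wide(df, schema))
  cols <- list(subject_id = "subject_id", analyte = "analyte", t_min = "t_min",
               value = "value", units = "units")
  for (k in names(schema)) cols[[k]] <- schema[[k]]
  need <- unlist(cols[c("subject_id", "analyte", "t_min", "value")])
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    hpa_stop(paste("missing required column(s):", paste(miss, collapse = ", ")), "schema_error")
  }
  out <- lapply(split(df, df[[cols$subject_id]]), function(sub) {
    series <- lapply(split(sub, sub[[cols$analyte]]), function(d) {
      d <- d[order(d[[cols$t_min]]), ]
      un <- if (cols$units %in% names(d) && !all(is.na(d[[cols$units]])) && nzchar(d[[cols$units]][1]))
        d[[cols$units]][1] else analyte_units(d[[cols$analyte]][1])
      hpa_ts(d[[cols$value]], t = d[[cols$t_min]], units = un,
             name = d[[cols$analyte]][1])
    })
    if (!all(c("ACTH", "cortisol") %in% names(series))) {
      hpa_stop("panel must contain ACTH and cortisol series per subject", "schema_error")
    }
    sw <- NULL
    if ("surgery_start" %in% names(sub) && !all(is.na(sub$surgery_start))) {
      sw <- c(sub$surgery_start[1], sub$surgery_end[1])
    }
    tr <- NULL
    if ("true_regime" %in% names(sub) && !all(is.na(sub$true_regime)) &&
        nzchar(sub$true_regime[1])) {
      tr <- sub$true_regime[1]
    }
    subject_profile(sub[[cols$subject_id]][1], acth = series$ACTH,
                    cortisol = series$cortisol,
                    cytokines = series[intersect(names(series), CYTOKINE_NAMES)],
                    surgery_window = sw, true_regime = tr)
  })
  unname(out)
}

read_panel_wide <- function(df, schema) {
  tcol <- schema$t_min %||% "t_min"
  sid <- schema$subject_id %||% "subject"
  if (!tcol %in% names(df)) {
    hpa_stop(paste("missing required time column:", tcol), "schema_error")
  }
  analytes <- setdiff(names(df), tcol)
  if (!length(analytes)) hpa_stop("wide file has a time column only", "schema_error")
  series <- lapply(analytes, function(an) {
    hpa_ts(df[[an]], t = df[[tcol]], units = analyte_units(an), name = an)
  })
  names(series) <- analytes
  if (!all(c("ACTH", "cortisol") %in% analytes)) {
    hpa_stop("wide panel must contain ACTH and cortisol columns", "schema_error")
  }
  list(subject_profile(sid, acth = series$ACTH, cortisol = series$cortisol,
                       cytokines = series[intersect(analytes, CYTOKINE_NAMES)]))
}
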