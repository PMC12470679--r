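# Structured LI-RADS report rendering and flat registry export.

REPORT_MANDATORY <- c("study_id", "hu_lesion", "hu_liver", "diam_by_phase",
                      "major", "result")

#' Assemble a report context
#'
#' Everything the structured report and the registry row need for one
#' lesion: identifiers, per-phase densities and sizes, the computed major
#' features, ancillary entries and the classification result.
#'
#' @param study_id character identifier.
#' @param hu_lesion,hu_liver named per-phase mean HU vectors (names from
#'   `native`, `arterial`, `portal_venous`, `delayed`; missing phases `NA`).
#' @param diam_by_phase named per-phase max axial diameters (mm).
#' @param major a [major_features] result.
#' @param result a [classify_lirads] result.
#' @param ancillary an [ancillary_features] object or `NULL`.
#' @param acquisition_date study date.
#' @return an object of class `report_context`.
#' @export
report_context <- function(study_id, hu_lesion, hu_liver, diam_by_phase,
                           major, result, ancillary = NULL,
                           acquisition_date = Sys.Date()) {
  structure(list(study_id = study_id, hu_lesion = hu_lesion,
                 hu_liver = hu_liver, diam_by_phase = diam_by_phase,
                 major = major, result = result, ancillary = ancillary,
                 acquisition_date = as.Date(acquisition_date)),
            class = "report_context")
}

default_report_template <- function(ctx) {
  m <- ctx$major; res <- ctx$result
  fmt1 <- function(x) ifelse(is.na(x), "n/a", sprintf("%.1f", x))
  phase_label <- c(native = "Native", arterial = "Arterial",
                   portal_venous = "Portal venous", delayed = "Late venous")
  lines <- c(
    "LI-RADS structured report",
    sprintf("Study: %s  (acquired %s)", ctx$study_id, format(ctx$acquisition_date)),
    "",
    "Densities (mean HU) and max axial diameter per phase:",
    sprintf("  %-14s liver %7s  lesion %7s  diameter %s mm",
            paste0(phase_label[PHASES], ":"),
            fmt1(vapply(PHASES, function(p) if (p %in% names(ctx$hu_liver)) ctx$hu_liver[[p]] else NA_real_, 0)),
            fmt1(vapply(PHASES, function(p) if (p %in% names(ctx$hu_lesion)) ctx$hu_lesion[[p]] else NA_real_, 0)),
            fmt1(vapply(PHASES, function(p) if (p %in% names(ctx$diam_by_phase)) ctx$diam_by_phase[[p]] else NA_real_, 0))),
    "",
    "Major features:",
    sprintf("  APHE: %s%s", m$aphe,
            if (is.na(m$aphe_delta_hu)) "" else sprintf(" (delta = %+.1f HU)", m$aphe_delta_hu)),
    sprintf("  Non-peripheral washout: %s%s", m$washout,
            if (is.na(m$par_used)) "" else sprintf(" (PAR %.1f%% in %s phase; pv %.1f%%, del %.1f%%)",
                                                   100 * m$par_used,
                                                   sub("_", " ", m$washout_phase),
                                                   100 * m$par_pv, 100 * m$par_del)),
    sprintf("  Enhancing capsule: %s", m$capsule),
    sprintf("  Threshold growth: %s (%s)", m$threshold_growth, m$growth_reason),
    sprintf("  Size: %.1f mm, measured in the %s phase",
            m$size_mm, sub("_", " ", m$size_phase))
  )
  if (!is.null(ctx$ancillary)) {
    yes_m <- names(ctx$ancillary$favoring_malignancy)[
      vapply(ctx$ancillary$favoring_malignancy, tristate_yes, TRUE)]
    yes_b <- names(ctx$ancillary$favoring_benignity)[
      vapply(ctx$ancillary$favoring_benignity, tristate_yes, TRUE)]
    lines <- c(lines, "",
               sprintf("Ancillary features favouring malignancy: %s",
                       if (length(yes_m)) paste(yes_m, collapse = ", ") else "none"),
               sprintf("Ancillary features favouring benignity: %s",
                       if (length(yes_b)) paste(yes_b, collapse = ", ") else "none"))
  }
  lines <- c(lines, "",
             sprintf("LI-RADS category: %s (base %s)", res$category, res$base_category),
             paste0("  Rationale: ", res$rationale))
  paste(lines, collapse = "\n")
}

#' Render the structured report
#'
#' Deterministic plain text built from the context: two renders of the same
#' context are byte-identical. The template is swappable (a function taking
#' the context and returning a single string).
#'
#' @param ctx a [report_context].
#' @param template report builder; defaults to the built-in English layout.
#' @return a single character string.
#' @export
render_report <- function(ctx, template = default_report_template) {
  miss <- REPORT_MANDATORY[vapply(REPORT_MANDATORY,
                                  function(f) is.null(ctx[[f]]), TRUE)]
  if (length(miss))
    lirads_abort(sprintf("report context is missing mandatory field(s): %s",
                         paste(miss, collapse = ", ")),
                 "lirads_report_error")
  template(ctx)
}

REGISTRY_COLS <- c(
  "study_id", "acquisition_date",
  "hu_liver_native", "hu_liver_art", "hu_liver_pv", "hu_liver_del",
  "hu_lesion_native", "hu_lesion_art", "hu_lesion_pv", "hu_lesion_del",
  "diam_native", "diam_art", "diam_pv", "diam_del",
  "size_mm", "size_phase", "aphe_delta", "aphe", "par_pv", "par_del",
  "washout", "washout_phase", "capsule", "growth_fraction",
  "threshold_growth", "category", "base_category"
)

#' Append one lesion to a flat registry CSV
#'
#' One lesion per row, schema-stable: appending to an existing file whose
#' header differs from the registry schema is an error.
#'
#' @param ctx a [report_context].
#' @param path registry CSV path (created with a header if absent).
#' @return invisibly, the written row as a data.frame.
#' @export
export_registry_row <- function(ctx, path) {
  m <- ctx$major
  g <- function(v, p) if (p %in% names(v)) as.numeric(v[[p]]) else NA_real_
  row <- data.frame(
    study_id = ctx$study_id,
    acquisition_date = format(ctx$acquisition_date, "%Y-%m-%d"),
    hu_liver_native = g(ctx$hu_liver, "native"), hu_liver_art = g(ctx$hu_liver, "arterial"),
    hu_liver_pv = g(ctx$hu_liver, "portal_venous"), hu_liver_del = g(ctx$hu_liver, "delayed"),
    hu_lesion_native = g(ctx$hu_lesion, "native"), hu_lesion_art = g(ctx$hu_lesion, "arterial"),
    hu_lesion_pv = g(ctx$hu_lesion, "portal_venous"), hu_lesion_del = g(ctx$hu_lesion, "delayed"),
    diam_native = g(ctx$diam_by_phase, "native"), diam_art = g(ctx$diam_by_phase, "arterial"),
    diam_pv = g(ctx$diam_by_phase, "portal_venous"), diam_del = g(ctx$diam_by_phase, "delayed"),
    size_mm = m$size_mm, size_phase = m$size_phase,
    aphe_delta = m$aphe_delta_hu, aphe = m$aphe,
    par_pv = m$par_pv, par_del = m$par_del,
    washout = m$washout, washout_phase = m$washout_phase,
    capsule = m$capsule, growth_fraction = m$growth_fraction,
    threshold_growth = m$threshold_growth,
    category = ctx$result$category, base_category = ctx$result$base_category,
    stringsAsFactors = FALSE
  )[, REGISTRY_COLS]
  if (file.exists(path)) {
    header <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
    if (!identical(header, REGISTRY_COLS))
      lirads_abort("registry header does not match the schema; refusing to append",
                   "lirads_report_error")
    utils::write.table(row, path, sep = ",", row.names = FALSE,
                       col.names = FALSE, append = TRUE, na = "")
  } else {
    utils::write.table(row, path, sep = ",", row.names = FALSE,
                       col.names = TRUE, na = "")
  }
  invisible(row)
}
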