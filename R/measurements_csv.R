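# Measurement-exchange CSV: one row per lesion, fixed column dialect so
# downstream spreadsheets and registries stay bit-stable.

MEASUREMENT_COLS <- c(
  "lesion_id",
  "hu_lesion_native", "hu_lesion_art", "hu_lesion_pv", "hu_lesion_del",
  "hu_liver_native", "hu_liver_art", "hu_liver_pv", "hu_liver_del",
  "diam_native", "diam_art", "diam_pv", "diam_del",
  "capsule", "prior_diam_mm", "prior_interval_days"
)

HU_COLS <- grep("^hu_", MEASUREMENT_COLS, value = TRUE)
NUM_COLS <- c(HU_COLS, grep("^diam_", MEASUREMENT_COLS, value = TRUE),
              "prior_diam_mm", "prior_interval_days")

#' Create a lesion measurement record
#'
#' One row of the measurement-exchange table: per-phase lesion and background
#' liver mean densities (HU), per-phase maximum axial diameters (mm), the
#' manually assessed capsule tristate and an optional prior-exam measurement
#' for threshold growth. Missing phases are `NA`.
#'
#' @param lesion_id character identifier.
#' @param hu_lesion,hu_liver named numeric vectors with any of the names
#'   `native`, `art`, `pv`, `del` (mean HU).
#' @param diam named numeric vector as above (max axial diameter, mm,
#'   non-negative).
#' @param capsule tristate token (`yes`/`no`/`not_evaluable`).
#' @param prior_diam_mm,prior_interval_days optional prior-exam diameter and
#'   interval in days (both present or both absent).
#' @return a one-row data.frame with the fixed column set.
#' @export
measurement_record <- function(lesion_id, hu_lesion = c(), hu_liver = c(),
                               diam = c(), capsule = "not_evaluable",
                               prior_diam_mm = NA_real_,
                               prior_interval_days = NA_real_) {
  as_tristate(capsule, "capsule")
  pick <- function(v, ph) if (ph %in% names(v)) as.numeric(v[[ph]]) else NA_real_
  d <- vapply(c("native", "art", "pv", "del"), function(ph) pick(diam, ph), 0)
  if (any(d < 0, na.rm = TRUE))
    lirads_abort("diameters must be >= 0", "lirads_format_error")
  df <- data.frame(
    lesion_id = as.character(lesion_id),
    hu_lesion_native = pick(hu_lesion, "native"), hu_lesion_art = pick(hu_lesion, "art"),
    hu_lesion_pv = pick(hu_lesion, "pv"), hu_lesion_del = pick(hu_lesion, "del"),
    hu_liver_native = pick(hu_liver, "native"), hu_liver_art = pick(hu_liver, "art"),
    hu_liver_pv = pick(hu_liver, "pv"), hu_liver_del = pick(hu_liver, "del"),
    diam_native = d[[1]], diam_art = d[[2]], diam_pv = d[[3]], diam_del = d[[4]],
    capsule = capsule,
    prior_diam_mm = as.numeric(prior_diam_mm),
    prior_interval_days = as.numeric(prior_interval_days),
    stringsAsFactors = FALSE
  )
  df[, MEASUREMENT_COLS]
}

#' Read / write the measurement-exchange CSV
#'
#' Comma-separated, decimal point, UTF-8, header row required. Writing then
#' reading is the identity for all finite values at 4 decimal places.
#'
#' @param path CSV file path.
#' @return `read_measurements_csv`: a data.frame with the fixed column set,
#'   one row per lesion.
#' @export
read_measurements_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(MEASUREMENT_COLS, names(df))
  if (length(miss))
    lirads_abort(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")),
                 "lirads_format_error")
  df <- df[, MEASUREMENT_COLS]
  for (col in NUM_COLS) {
    v <- df[[col]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & nzchar(v) & is.na(conv))
      if (length(bad))
        lirads_abort(sprintf("non-numeric value in column %s at row %d", col, bad[1]),
                     "lirads_format_error")
      df[[col]] <- conv
    } else df[[col]] <- as.numeric(v)
  }
  for (i in seq_len(nrow(df))) as_tristate(df$capsule[i], sprintf("capsule (row %d)", i))
  df$lesion_id <- as.character(df$lesion_id)
  df
}

#' @rdname read_measurements_csv
#' @param records data.frame of measurement records (fixed column set).
#' @export
write_measurements_csv <- function(records, path) {
  miss <- setdiff(MEASUREMENT_COLS, names(records))
  if (length(miss))
    lirads_abort(sprintf("missing required column(s): %s", paste(miss, collapse = ", ")),
                 "lirads_format_error")
  out <- records[, MEASUREMENT_COLS]
  for (col in NUM_COLS) out[[col]] <- round(as.numeric(out[[col]]), 4)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}
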