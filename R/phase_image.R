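# Container for one contrast phase of a co-registered multi-phase CT study.

#' Construct a phase image
#'
#' A `phase_image` bundles a 3D array of Hounsfield Units with its voxel
#' spacing, the contrast-phase label and the acquisition date. Axial slices
#' run along the third array axis; the physical coordinate of voxel
#' `(i, j, k)` is `(i-1, j-1, k-1) * spacing_mm`.
#'
#' @param hu numeric 3D array of Hounsfield Units (finite).
#' @param spacing_mm positive numeric vector of length 3, voxel size in mm.
#' @param phase one of `"native"`, `"arterial"`, `"portal_venous"`,
#'   `"delayed"`.
#' @param acquisition_date a `Date` (or string coercible to one).
#' @return an object of class `phase_image`.
#' @export
phase_image <- function(hu, spacing_mm, phase, acquisition_date = Sys.Date()) {
  if (!is.array(hu) || length(dim(hu)) != 3L)
    lirads_abort("hu must be a 3D array", "lirads_format_error")
  if (!all(is.finite(hu)))
    lirads_abort("hu contains non-finite values", "lirads_format_error")
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    lirads_abort("spacing_mm must be 3 positive numbers", "lirads_format_error")
  if (length(phase) != 1L || !phase %in% PHASES)
    lirads_abort(sprintf("unknown phase label %s (expected one of %s)",
                         deparse(phase), paste(PHASES, collapse = ", ")),
                 "lirads_format_error")
  structure(
    list(hu = hu, spacing_mm = as.numeric(spacing_mm), phase = phase,
         acquisition_date = as.Date(acquisition_date)),
    class = "phase_image"
  )
}

#' @export
print.phase_image <- function(x, ...) {
  cat(sprintf("<phase_image> %s  %s voxels  spacing %s mm  acquired %s\n",
              x$phase, paste(dim(x$hu), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"),
              format(x$acquisition_date)))
  cat(sprintf("  HU range [%.1f, %.1f], mean %.1f\n",
              min(x$hu), max(x$hu), mean(x$hu)))
  invisible(x)
}

#' Read a co-registered multi-phase CT study from NIfTI files
#'
#' Loads between one and four phases. All phases must share the same array
#' shape and voxel spacing (the co-registration contract); a mismatch raises
#' a registration error. A washout assessment downstream needs at least one
#' venous phase and the arterial phase; missing phases are simply absent from
#' the returned list and are flagged as not evaluable by the quantification
#' step.
#'
#' @param paths named character vector of NIfTI file paths; names are phase
#'   labels (`native`, `arterial`, `portal_venous`, `delayed`).
#' @param sidecar optional path to a JSON sidecar mapping phase label to
#'   ISO-8601 acquisition date; phases absent from the sidecar get today's
#'   date.
#' @return named list of [phase_image] objects.
#' @export
read_study <- function(paths, sidecar = NULL) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    lirads_abort("paths must be named by phase label", "lirads_format_error")
  bad <- setdiff(names(paths), PHASES)
  if (length(bad))
    lirads_abort(sprintf("unknown phase label(s): %s", paste(bad, collapse = ", ")),
                 "lirads_format_error")
  missing <- !file.exists(paths)
  if (any(missing))
    lirads_abort(sprintf("file not found: %s", paste(paths[missing], collapse = ", ")),
                 "lirads_io_error")
  dates <- list()
  if (!is.null(sidecar)) dates <- jsonlite::read_json(sidecar, simplifyVector = TRUE)

  study <- list()
  ref_dim <- NULL; ref_sp <- NULL
  for (ph in names(paths)) {
    img <- RNifti::readNifti(paths[[ph]])
    sp <- RNifti::pixdim(img)[1:3]
    arr <- array(as.numeric(img), dim = dim(img))
    if (is.null(ref_dim)) { ref_dim <- dim(arr); ref_sp <- sp }
    else if (!identical(dim(arr), ref_dim) || max(abs(sp - ref_sp)) > 1e-6)
      lirads_abort(
        sprintf("phase %s is not co-registered: shape/spacing differs from %s",
                ph, names(paths)[1]),
        "lirads_registration_error")
    date <- if (!is.null(dates[[ph]])) as.Date(dates[[ph]]) else Sys.Date()
    study[[ph]] <- phase_image(arr, sp, ph, date)
  }
  study
}

#' Write a multi-phase study as NIfTI volumes plus a JSON date sidecar
#'
#' One file per phase, named `<prefix>_<suffix>.nii.gz` with suffixes
#' `native`, `art`, `pv`, `del`; acquisition dates go to
#' `<prefix>_dates.json` (ISO-8601).
#'
#' @param study named list of [phase_image] objects.
#' @param prefix output path prefix.
#' @return invisibly, the named vector of written volume paths.
#' @export
write_study <- function(study, prefix) {
  suffix <- c(native = "native", arterial = "art", portal_venous = "pv",
              delayed = "del")
  out <- character(0)
  dates <- list()
  for (ph in names(study)) {
    p <- study[[ph]]
    f <- sprintf("%s_%s.nii.gz", prefix, suffix[[ph]])
    img <- RNifti::asNifti(p$hu)
    RNifti::pixdim(img) <- p$spacing_mm
    RNifti::writeNifti(img, f)
    out[[ph]] <- f
    dates[[ph]] <- format(p$acquisition_date, "%Y-%m-%d")
  }
  jsonlite::write_json(dates, paste0(prefix, "_dates.json"), auto_unbox = TRUE)
  invisible(out)
}
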