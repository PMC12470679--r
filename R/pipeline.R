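# End-to-end orchestration: read -> segment -> background ROIs -> features
# -> classify -> report.

RUN_CONFIG_KEYS <- c(
  "paths", "sidecar", "study", "study_id", "seed_center_mm", "seed_radius_mm",
  "seed_phase", "k", "liver_roi_centers_mm", "capsule", "ancillary_malignancy",
  "ancillary_benignity", "best_phase", "prior_diam_mm", "prior_interval_days",
  "manual_mask", "out_dir", "rng_seed"
)

#' Validate a pipeline run configuration
#'
#' Accepts a list or a YAML/JSON file path. Unknown keys are rejected; the
#' seed sphere and best phase are mandatory.
#'
#' @param config list of run options, or a path to a YAML/JSON file.
#' @return the validated config list (class `run_config`).
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown))
    lirads_abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
                 "lirads_config_error")
  if (is.null(config[["study"]]) && is.null(config[["paths"]]))
    lirads_abort("config needs either in-memory phases ('study') or file 'paths'",
                 "lirads_config_error")
  if (is.null(config$manual_mask) &&
      (is.null(config$seed_center_mm) || is.null(config$seed_radius_mm)))
    lirads_abort("config needs a seed sphere (seed_center_mm, seed_radius_mm) or a manual_mask",
                 "lirads_config_error")
  if (is.null(config$best_phase))
    lirads_abort("config needs best_phase for size measurement", "lirads_config_error")
  defaults <- list(seed_phase = "arterial", k = 2.5, capsule = "not_evaluable",
                   study_id = "lesion-1")
  for (nm in names(defaults)) if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  structure(config, class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, lirads_error = function(e) {
    e$message <- sprintf("[stage %s] %s", name, conditionMessage(e))
    stop(e)
  })
}

#' Run the full quantification pipeline on one study
#'
#' Executes: load phases (co-registration checked) -> sphere-seeded
#' segmentation on the seed phase (or use the manual-override mask) ->
#' background liver ROIs -> per-phase lesion measurements -> arithmetic
#' major features -> LI-RADS v2018 classification -> structured report.
#' With `out_dir` set, writes the mask (NIfTI), measurement CSV, feature
#' JSON, report text and a JSON run log of versions and parameters.
#'
#' @param config a [run_config] (or list / YAML / JSON path accepted by it).
#' @return an object of class `lirads_run` with elements `mask`,
#'   `measurements`, `background`, `features`, `result`, `report`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)

  study <- stage("read", {
    if (!is.null(cfg[["study"]])) cfg[["study"]]
    else read_study(unlist(cfg$paths), cfg$sidecar)
  })

  mask <- stage("segment", {
    if (!is.null(cfg$manual_mask)) {
      mm <- cfg$manual_mask
      if (inherits(mm, "lesion_mask")) mm else read_mask(mm)
    } else {
      seed <- sphere_seed(cfg$seed_center_mm, cfg$seed_radius_mm, cfg$seed_phase)
      seg_phase <- if (cfg$seed_phase %in% names(study)) cfg$seed_phase else names(study)[1]
      segment_sphere_seed(study[[seg_phase]], seed, k = cfg$k)
    }
  })

  measurements <- stage("measure", measure_study(study, mask))
  background <- stage("background",
                      background_liver(study, cfg$liver_roi_centers_mm))

  features <- stage("quantify", {
    hu_lesion <- vapply(measurements, function(m) m$mean_hu, 0)
    diam <- vapply(measurements, function(m) m$max_axial_diameter_mm, 0)
    major_features(
      hu_lesion = hu_lesion, hu_liver = background[names(study)],
      diam_by_phase = diam, chosen_phase = cfg$best_phase,
      capsule = cfg$capsule,
      prior_diam_mm = cfg$prior_diam_mm,
      prior_interval_days = cfg$prior_interval_days
    )
  })

  ancillary <- NULL
  if (!is.null(cfg$ancillary_malignancy) || !is.null(cfg$ancillary_benignity))
    ancillary <- ancillary_features(
      if (is.null(cfg$ancillary_malignancy)) character(0) else unlist(cfg$ancillary_malignancy),
      if (is.null(cfg$ancillary_benignity)) character(0) else unlist(cfg$ancillary_benignity))

  result <- stage("classify", classify_lirads(features, ancillary))

  ctx <- report_context(
    study_id = cfg$study_id,
    hu_lesion = vapply(measurements, function(m) m$mean_hu, 0),
    hu_liver = background[names(study)],
    diam_by_phase = vapply(measurements, function(m) m$max_axial_diameter_mm, 0),
    major = features, result = result, ancillary = ancillary,
    acquisition_date = study[[1]]$acquisition_date
  )
  report <- stage("report", render_report(ctx))

  run <- structure(list(
    study_id = cfg$study_id, mask = mask, measurements = measurements,
    background = background, features = features, result = result,
    context = ctx, report = report
  ), class = "lirads_run")

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    pre <- file.path(cfg$out_dir, cfg$study_id)
    write_mask(mask, paste0(pre, "_mask.nii.gz"), study[[1]]$spacing_mm)
    rec <- measurement_record(
      lesion_id = cfg$study_id,
      hu_lesion = stats::setNames(ctx$hu_lesion,
        c(native = "native", arterial = "art", portal_venous = "pv",
          delayed = "del")[names(ctx$hu_lesion)]),
      hu_liver = stats::setNames(ctx$hu_liver,
        c(native = "native", arterial = "art", portal_venous = "pv",
          delayed = "del")[names(ctx$hu_liver)]),
      diam = stats::setNames(ctx$diam_by_phase,
        c(native = "native", arterial = "art", portal_venous = "pv",
          delayed = "del")[names(ctx$diam_by_phase)]),
      capsule = cfg$capsule,
      prior_diam_mm = if (is.null(cfg$prior_diam_mm)) NA_real_ else cfg$prior_diam_mm,
      prior_interval_days = if (is.null(cfg$prior_interval_days)) NA_real_ else cfg$prior_interval_days
    )
    write_measurements_csv(rec, paste0(pre, "_measurements.csv"))
    jsonlite::write_json(
      list(features = unclass(features), result = unclass(result)),
      paste0(pre, "_features.json"), auto_unbox = TRUE, digits = NA, na = "null")
    writeLines(report, paste0(pre, "_report.txt"))
    jsonlite::write_json(list(
      package = "liradsq",
      version = as.character(utils::packageVersion("liradsq")),
      parameters = cfg[setdiff(names(cfg), c("study", "manual_mask"))]
    ), paste0(pre, "_runlog.json"), auto_unbox = TRUE, na = "null", force = TRUE)
  }
  run
}

#' @export
print.lirads_run <- function(x, ...) {
  cat(sprintf("<lirads_run> %s: %s\n", x$study_id, x$result$category))
  print(x$features)
  invisible(x)
}
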