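# Arithmetic derivation of the LI-RADS major features from mean densities.
#
# APHE: lesion-minus-liver mean HU difference in the arterial phase; any
# strictly positive difference counts as hyperenhancement. Washout: the
# percentage attenuation ratio PAR = liver HU / lesion HU in a venous phase;
# washout needs to be present in only one venous phase, so the higher of the
# two PARs decides, with PAR strictly > 1 (i.e. > 100%) counting as washout.
# Ties classify negative at both boundaries. HU values are carried at full
# float precision; nothing is rounded before comparison.

#' Background liver density from two circular ROIs
#'
#' The background liver mean HU per phase is the average of two circular
#' ROI means (2 cm diameter by default), one in the left and one in the
#' right liver lobe, each taken on the single axial slice through its
#' centre.
#'
#' @param study named list of [phase_image] objects.
#' @param roi_centers_mm list of two numeric length-3 physical points. If
#'   `NULL`, two fixed offsets from the volume centre are used — a fallback
#'   intended for phantom volumes whose background is liver everywhere, not
#'   for clinical images, where ROI placement is the reader's.
#' @param diameter_mm ROI diameter (default 20 mm).
#' @return named numeric vector of per-phase background liver mean HU, with
#'   the ROI centres as attribute `roi_centers_mm`.
#' @export
background_liver <- function(study, roi_centers_mm = NULL, diameter_mm = 20) {
  ref <- study[[1]]
  d <- dim(ref$hu); sp <- ref$spacing_mm
  if (is.null(roi_centers_mm)) {
    # phantom fallback: two lateral ROIs on a low slice, clear of a
    # volume-centred lesion
    ext <- (d - 1) * sp
    roi_centers_mm <- list(c(0.2 * ext[1], 0.5 * ext[2], 0.1 * ext[3]),
                           c(0.8 * ext[1], 0.5 * ext[2], 0.1 * ext[3]))
  }
  if (length(roi_centers_mm) != 2L)
    lirads_abort("exactly two ROI centres are required (left and right lobe)",
                 "lirads_config_error")
  r <- diameter_mm / 2
  roi_idx <- lapply(roi_centers_mm, function(ctr) {
    cvox <- round(mm_to_voxel(ctr, sp))
    if (any(cvox < 1) || any(cvox > d))
      lirads_abort("ROI centre lies outside the volume", "lirads_config_error")
    gx <- (seq_len(d[1]) - 1) * sp[1] - ctr[1]
    gy <- (seq_len(d[2]) - 1) * sp[2] - ctr[2]
    disk <- outer(gx^2, gy^2, `+`) <= r^2
    list(disk = disk, z = cvox[3])
  })
  out <- vapply(study, function(p) {
    mean(vapply(roi_idx, function(roi) mean(p$hu[, , roi$z][roi$disk]), 0))
  }, 0)
  attr(out, "roi_centers_mm") <- roi_centers_mm
  out
}

#' Arterial-phase hyperenhancement from mean densities
#'
#' @param lesion_art_hu,liver_art_hu mean HU of the lesion and of the
#'   background liver in the arterial phase. `NA` (phase missing) yields a
#'   not-evaluable result rather than "no".
#' @return list with `delta` (lesion minus liver, HU) and `aphe`, a tristate
#'   token: `"yes"` iff `delta > 0` (strict).
#' @export
compute_aphe <- function(lesion_art_hu, liver_art_hu) {
  if (is.na(lesion_art_hu) || is.na(liver_art_hu))
    return(list(delta = NA_real_, aphe = "not_evaluable"))
  delta <- lesion_art_hu - liver_art_hu
  list(delta = delta, aphe = if (delta > 0) "yes" else "no")
}

#' Percentage attenuation ratio
#'
#' PAR = background-liver mean HU / lesion mean HU in a venous phase;
#' dimensionless, with 1.0 = isodense (100%).
#'
#' @param liver_hu,lesion_hu mean HU values; `lesion_hu` must be strictly
#'   positive (a non-positive lesion mean makes the ratio sign-meaningless).
#' @return the ratio (multiply by 100 for the percent scale).
#' @export
compute_par <- function(liver_hu, lesion_hu) {
  if (is.na(liver_hu) || is.na(lesion_hu)) return(NA_real_)
  if (lesion_hu <= 0)
    lirads_abort("PAR undefined: lesion mean HU must be > 0", "lirads_par_error")
  liver_hu / lesion_hu
}

#' Assess non-peripheral washout from the two venous-phase PARs
#'
#' Washout needs to be present in only one venous phase, so the higher of
#' the available PAR values decides: washout iff max PAR > 1, strictly.
#'
#' @param par_pv,par_del PAR of the portal venous and delayed phase (`NA`
#'   if the phase is missing).
#' @return list with `washout` (tristate), `par_used`, `phase_used`.
#' @export
assess_washout <- function(par_pv = NA_real_, par_del = NA_real_) {
  avail <- c(portal_venous = par_pv, delayed = par_del)
  avail <- avail[!is.na(avail)]
  if (!length(avail))
    return(list(washout = "not_evaluable", par_used = NA_real_,
                phase_used = NA_character_))
  i <- which.max(avail)
  list(washout = if (avail[[i]] > 1) "yes" else "no",
       par_used = unname(avail[[i]]),
       phase_used = names(avail)[i])
}

#' Assess threshold growth
#'
#' Threshold growth is a diameter increase of at least 50% within at most 6
#' months (183 days), measured in the same phase and plane — the phase/plane
#' identity of the two measurements is a declared input the caller asserts.
#' Without a prior examination in the last six months the result is "no".
#'
#' @param current_diam_mm current maximum diameter (> 0).
#' @param prior_diam_mm prior-exam diameter (> 0), or `NULL` if none.
#' @param interval_days days between the two exams (> 0).
#' @return list with `growth` (tristate `"yes"`/`"no"`), `fraction`
#'   (relative increase, `NA` when no qualifying prior), and `reason`.
#' @export
assess_threshold_growth <- function(current_diam_mm, prior_diam_mm = NULL,
                                    interval_days = NULL) {
  if (is.na(current_diam_mm) || current_diam_mm <= 0)
    lirads_abort("current diameter must be > 0", "lirads_format_error")
  no_prior <- is.null(prior_diam_mm) || is.na(prior_diam_mm)
  if (no_prior || is.null(interval_days) || is.na(interval_days))
    return(list(growth = "no", fraction = NA_real_,
                reason = "no prior examination"))
  if (prior_diam_mm <= 0 || interval_days <= 0)
    lirads_abort("prior diameter and interval must be > 0", "lirads_format_error")
  if (interval_days > 183)
    return(list(growth = "no", fraction = NA_real_,
                reason = sprintf("prior examination %d days ago (> 6 months)",
                                 round(interval_days))))
  fraction <- (current_diam_mm - prior_diam_mm) / prior_diam_mm
  list(growth = if (fraction >= 0.5) "yes" else "no",
       fraction = fraction,
       reason = sprintf("%+.0f%% in %d days", 100 * fraction, round(interval_days)))
}

#' Select the size measurement from the chosen best phase
#'
#' Size should be taken in the phase where the lesion margins are best
#' delineated; the choice is the reader's. Choosing the arterial phase
#' triggers a warning, as arterial-phase sizing tends to overestimate.
#'
#' @param diam_by_phase named numeric vector of max axial diameters (mm) per
#'   phase (names from `native`, `arterial`, `portal_venous`, `delayed`).
#' @param chosen_phase the reader's best phase.
#' @return list with `size_mm` and `phase`.
#' @export
select_size <- function(diam_by_phase, chosen_phase) {
  if (!chosen_phase %in% names(diam_by_phase) || is.na(diam_by_phase[[chosen_phase]]))
    lirads_abort(sprintf("no size measurement for phase %s", chosen_phase),
                 "lirads_format_error")
  if (chosen_phase == "arterial")
    lirads_warn("arterial phase chosen for size measurement: size may be overestimated",
                "lirads_size_phase_warning")
  list(size_mm = unname(diam_by_phase[[chosen_phase]]), phase = chosen_phase)
}

size_bin <- function(size_mm) {
  if (size_mm < 10) "<10" else if (size_mm < 20) "10-19" else ">=20"
}

#' Assemble the major-feature set for one lesion
#'
#' Bundles the arithmetic APHE and washout results with the manual capsule
#' entry, threshold growth, and the size from the chosen phase.
#'
#' @param hu_lesion,hu_liver named numeric vectors of mean HU with any of
#'   the names `native`, `arterial` (or `art`), `portal_venous` (or `pv`),
#'   `delayed` (or `del`); `NA`/absent phases propagate to not-evaluable
#'   features.
#' @param diam_by_phase named vector of per-phase diameters (mm).
#' @param chosen_phase best phase for sizing.
#' @param capsule manual tristate entry.
#' @param prior_diam_mm,prior_interval_days optional prior exam for
#'   threshold growth.
#' @return an object of class `major_feature_set`.
#' @export
major_features <- function(hu_lesion, hu_liver, diam_by_phase, chosen_phase,
                           capsule = "not_evaluable",
                           prior_diam_mm = NULL, prior_interval_days = NULL) {
  as_tristate(capsule, "capsule")
  norm <- function(v) {
    nm <- names(v)
    nm[nm == "art"] <- "arterial"; nm[nm == "pv"] <- "portal_venous"
    nm[nm == "del"] <- "delayed"
    names(v) <- nm
    v
  }
  hu_lesion <- norm(hu_lesion); hu_liver <- norm(hu_liver)
  diam_by_phase <- norm(diam_by_phase)
  get <- function(v, ph) if (ph %in% names(v)) v[[ph]] else NA_real_

  aphe <- compute_aphe(get(hu_lesion, "arterial"), get(hu_liver, "arterial"))
  par_pv <- if (!is.na(get(hu_lesion, "portal_venous")) &&
                !is.na(get(hu_liver, "portal_venous")))
    compute_par(get(hu_liver, "portal_venous"), get(hu_lesion, "portal_venous"))
  else NA_real_
  par_del <- if (!is.na(get(hu_lesion, "delayed")) &&
                 !is.na(get(hu_liver, "delayed")))
    compute_par(get(hu_liver, "delayed"), get(hu_lesion, "delayed"))
  else NA_real_
  washout <- assess_washout(par_pv, par_del)
  size <- select_size(diam_by_phase, chosen_phase)
  growth <- assess_threshold_growth(size$size_mm, prior_diam_mm, prior_interval_days)

  structure(list(
    aphe_delta_hu = aphe$delta, aphe = aphe$aphe,
    par_pv = par_pv, par_del = par_del,
    par_used = washout$par_used, washout_phase = washout$phase_used,
    washout = washout$washout,
    capsule = capsule,
    size_mm = size$size_mm, size_phase = size$phase,
    size_bin = size_bin(size$size_mm),
    threshold_growth = growth$growth, growth_fraction = growth$fraction,
    growth_reason = growth$reason
  ), class = "major_feature_set")
}

#' @export
print.major_feature_set <- function(x, ...) {
  cat("<major_feature_set>\n")
  cat(sprintf("  APHE: %s (delta = %s HU)\n", x$aphe,
              if (is.na(x$aphe_delta_hu)) "NA" else sprintf("%+.1f", x$aphe_delta_hu)))
  cat(sprintf("  Washout: %s (PAR pv %.3f, del %.3f; used %s)\n", x$washout,
              x$par_pv, x$par_del,
              if (is.na(x$washout_phase)) "none" else x$washout_phase))
  cat(sprintf("  Capsule: %s\n", x$capsule))
  cat(sprintf("  Size: %.1f mm (%s phase, bin %s)\n", x$size_mm, x$size_phase,
              x$size_bin))
  cat(sprintf("  Threshold growth: %s (%s)\n", x$threshold_growth, x$growth_reason))
  invisible(x)
}
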