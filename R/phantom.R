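# Synthetic four-phase CT phantom with known lesion ground truth.
#
# The phantom emulates a full CT-HCC protocol (native, arterial, portal
# venous, late/delayed venous) of a liver background with one embedded
# ellipsoidal lesion. Enhancement is controlled directly in the units the
# downstream arithmetic uses: an arterial lesion-minus-liver HU delta, and
# per-venous-phase percentage attenuation ratios (PAR = liver HU / lesion
# HU), so every ground-truth major-feature flag is known by construction.

#' Phantom configuration
#'
#' @param volume_shape integer vector of 3, voxels per axis.
#' @param spacing_mm voxel size per axis in mm.
#' @param liver_hu_by_phase named numeric vector: mean liver HU for
#'   `native`, `arterial`, `portal_venous`, `delayed`.
#' @param lesion_center_mm lesion centre in physical mm (default: volume
#'   centre).
#' @param lesion_radii_mm ellipsoid semi-axes in mm (all > 0).
#' @param aphe_delta_hu arterial-phase lesion-minus-liver HU difference;
#'   positive means arterial-phase hyperenhancement.
#' @param par_pv,par_del target percentage attenuation ratio (liver/lesion)
#'   in the portal venous and delayed phases; values > 1 mean washout.
#' @param native_offset_hu lesion-minus-liver HU offset in the native phase.
#' @param capsule logical: add an enhancing rim around the lesion in the
#'   venous phases.
#' @param capsule_thickness_mm,capsule_rim_hu rim thickness and HU offset
#'   added to rim voxels in the venous phases.
#' @param lobulation_amp fractional amplitude of a lobulated surface
#'   perturbation (sum of three low-order spherical harmonics); 0 keeps the
#'   lesion a pure ellipsoid. Used to exercise segmentation failure modes.
#' @param noise_sigma_hu SD of additive Gaussian voxel noise (>= 0).
#' @param rng_seed integer seed; identical config + seed gives bit-identical
#'   volumes.
#' @param prior_exam optional list `list(diameter_mm=, days_before=)`
#'   describing a prior measurement of the same lesion, used for the
#'   threshold-growth ground truth.
#' @param acquisition_date study date (all phases share it; co-registered).
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(volume_shape = c(80, 80, 64),
                           spacing_mm = c(1, 1, 1),
                           liver_hu_by_phase = c(native = 55, arterial = 75,
                                                 portal_venous = 110, delayed = 100),
                           lesion_center_mm = NULL,
                           lesion_radii_mm = c(16, 14, 12),
                           aphe_delta_hu = 25,
                           par_pv = 1.10,
                           par_del = 1.15,
                           native_offset_hu = -10,
                           capsule = FALSE,
                           capsule_thickness_mm = 2,
                           capsule_rim_hu = 30,
                           lobulation_amp = 0,
                           noise_sigma_hu = 10,
                           rng_seed = 1L,
                           prior_exam = NULL,
                           acquisition_date = as.Date("2024-01-01")) {
  if (any(lesion_radii_mm <= 0)) lirads_abort("all lesion radii must be > 0", "lirads_config_error")
  if (any(spacing_mm <= 0)) lirads_abort("spacing must be > 0", "lirads_config_error")
  if (par_pv <= 0 || par_del <= 0) lirads_abort("PAR targets must be > 0", "lirads_config_error")
  if (noise_sigma_hu < 0) lirads_abort("noise_sigma_hu must be >= 0", "lirads_config_error")
  if (!all(PHASES %in% names(liver_hu_by_phase)))
    lirads_abort("liver_hu_by_phase must name all four phases", "lirads_config_error")
  if (is.null(lesion_center_mm))
    lesion_center_mm <- (volume_shape - 1) * spacing_mm / 2
  if (!is.null(prior_exam) &&
      (is.null(prior_exam$diameter_mm) || is.null(prior_exam$days_before)))
    lirads_abort("prior_exam needs diameter_mm and days_before", "lirads_config_error")
  structure(list(
    volume_shape = as.integer(volume_shape), spacing_mm = as.numeric(spacing_mm),
    liver_hu_by_phase = liver_hu_by_phase[PHASES],
    lesion_center_mm = as.numeric(lesion_center_mm),
    lesion_radii_mm = as.numeric(lesion_radii_mm),
    aphe_delta_hu = aphe_delta_hu, par_pv = par_pv, par_del = par_del,
    native_offset_hu = native_offset_hu,
    capsule = isTRUE(capsule), capsule_thickness_mm = capsule_thickness_mm,
    capsule_rim_hu = capsule_rim_hu, lobulation_amp = lobulation_amp,
    noise_sigma_hu = noise_sigma_hu, rng_seed = as.integer(rng_seed),
    prior_exam = prior_exam, acquisition_date = as.Date(acquisition_date)
  ), class = "phantom_config")
}

# Lesion voxel mask; a lobulated perturbation modulates the normalized radius
# with three low-order real spherical harmonics.
phantom_lesion_mask <- function(cfg, extra_mm = 0) {
  dimv <- cfg$volume_shape; sp <- cfg$spacing_mm
  r <- cfg$lesion_radii_mm + extra_mm
  ux <- ((seq_len(dimv[1]) - 1) * sp[1] - cfg$lesion_center_mm[1]) / r[1]
  uy <- ((seq_len(dimv[2]) - 1) * sp[2] - cfg$lesion_center_mm[2]) / r[2]
  uz <- ((seq_len(dimv[3]) - 1) * sp[3] - cfg$lesion_center_mm[3]) / r[3]
  X <- array(ux, dimv)
  Y <- aperm(array(uy, dimv[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(uz, dimv[c(3, 1, 2)]), c(2, 3, 1))
  rho <- sqrt(X^2 + Y^2 + Z^2)
  if (cfg$lobulation_amp == 0) return(rho <= 1)
  theta <- acos(ifelse(rho > 0, Z / pmax(rho, 1e-12), 1))
  phi <- atan2(Y, X)
  harm <- (sin(2 * theta) * cos(phi) +
           sin(theta)^2 * sin(3 * phi) +
           (3 * cos(theta)^2 - 1) / 2) / 3
  rho <= 1 + cfg$lobulation_amp * harm
}

#' Generate a four-phase phantom study with ground truth
#'
#' Liver voxels are Normal(liver HU, sigma) per phase; lesion voxels are
#' Normal(target, sigma) with arterial target `liver + aphe_delta_hu`, venous
#' targets `liver / PAR`, and native target `liver + native_offset_hu`. The
#' lesion geometry is identical across phases (co-registered). With
#' `capsule = TRUE` a rim of the given thickness around the lesion gets the
#' rim HU offset in the two venous phases.
#'
#' @param config a [phantom_config].
#' @return a list with elements `study` (named list of four [phase_image]s)
#'   and `truth` (class `phantom_truth`: lesion mask, expected per-phase
#'   lesion mean HU, expected feature flags, expected max axial diameter).
#' @export
generate_phantom <- function(config) {
  cfg <- config
  dimv <- cfg$volume_shape; sp <- cfg$spacing_mm
  extent_mm <- (dimv - 1) * sp
  reach <- max(cfg$lesion_radii_mm) * (1 + abs(cfg$lobulation_amp)) +
    if (cfg$capsule) cfg$capsule_thickness_mm else 0
  for (a in 1:3) {
    ra <- cfg$lesion_radii_mm[a] * (1 + abs(cfg$lobulation_amp)) +
      if (cfg$capsule) cfg$capsule_thickness_mm else 0
    if (cfg$lesion_center_mm[a] - ra < 0 || cfg$lesion_center_mm[a] + ra > extent_mm[a])
      lirads_abort(sprintf("lesion extends outside the volume along axis %s",
                           c("x", "y", "z")[a]),
                   "lirads_config_error")
  }

  mask <- phantom_lesion_mask(cfg)
  rim <- NULL
  if (cfg$capsule) {
    rim <- phantom_lesion_mask(cfg, extra_mm = cfg$capsule_thickness_mm) & !mask
  }

  liver <- cfg$liver_hu_by_phase
  target <- c(
    native = unname(liver[["native"]]) + cfg$native_offset_hu,
    arterial = unname(liver[["arterial"]]) + cfg$aphe_delta_hu,
    portal_venous = unname(liver[["portal_venous"]]) / cfg$par_pv,
    delayed = unname(liver[["delayed"]]) / cfg$par_del
  )

  set.seed(cfg$rng_seed)
  study <- list()
  for (ph in PHASES) {
    vol <- array(liver[[ph]], dimv)
    vol[mask] <- target[[ph]]
    if (!is.null(rim) && ph %in% c("portal_venous", "delayed"))
      vol[rim] <- liver[[ph]] + cfg$capsule_rim_hu
    if (cfg$noise_sigma_hu > 0)
      vol <- vol + array(stats::rnorm(prod(dimv), 0, cfg$noise_sigma_hu), dimv)
    study[[ph]] <- phase_image(vol, sp, ph, cfg$acquisition_date)
  }

  diam <- mask_max_axial_diameter(mask, sp)
  growth <- "no"; growth_frac <- NA_real_
  if (!is.null(cfg$prior_exam) && cfg$prior_exam$days_before <= 183) {
    growth_frac <- (diam$diameter_mm - cfg$prior_exam$diameter_mm) / cfg$prior_exam$diameter_mm
    growth <- if (growth_frac >= 0.5) "yes" else "no"
  }
  truth <- structure(list(
    lesion_mask = mask,
    capsule_rim_mask = rim,
    expected_lesion_hu = target,
    expected_aphe = cfg$aphe_delta_hu > 0,
    expected_washout = max(cfg$par_pv, cfg$par_del) > 1,
    expected_capsule = cfg$capsule,
    expected_diameter_mm = diam$diameter_mm,
    expected_threshold_growth = growth,
    expected_growth_fraction = growth_frac
  ), class = "phantom_truth")

  list(study = study, truth = truth, config = cfg)
}

#' Generate a phantom cohort with feature prevalences
#'
#' Draws `n` independent single-lesion studies whose major features are
#' Bernoulli at the stated prevalences. Per-lesion enhancement parameters
#' are drawn from ranges typical of hypervascular HCC on multi-phase CT:
#' APHE-positive lesions enhance 10-50 HU above liver, washout-positive
#' lesions reach a delayed-phase PAR of 1.05-1.30 (portal venous PAR may
#' stay below 1, as washout is often confined to the late phase), and
#' lesion semi-axes span 7-16 mm so the cohort covers the 10-19 mm and
#' >= 20 mm size bins.
#'
#' @param n number of studies (>= 1).
#' @param feature_prevalences named numeric vector in `[0, 1]` with any of
#'   `aphe`, `washout`, `capsule`, `threshold_growth`.
#' @param rng_seed integer seed for the cohort draw.
#' @param volume_shape,spacing_mm,noise_sigma_hu passed to each phantom.
#' @param lesion_semiaxis_range_mm range the largest lesion semi-axis is
#'   drawn from (uniform); the other two semi-axes are 0.85-1 times it.
#' @return list of `n` elements, each as returned by [generate_phantom].
#' @export
phantom_cohort <- function(n,
                           feature_prevalences = c(aphe = 45/46, washout = 38/46,
                                                   capsule = 9/46, threshold_growth = 8/46),
                           rng_seed = 1L,
                           volume_shape = c(64, 64, 48),
                           spacing_mm = c(1, 1, 1),
                           noise_sigma_hu = 10,
                           lesion_semiaxis_range_mm = c(7, 16)) {
  if (n < 1) lirads_abort("n must be >= 1", "lirads_config_error")
  prev <- c(aphe = 0.9, washout = 0.8, capsule = 0.2, threshold_growth = 0.2)
  prev[names(feature_prevalences)] <- feature_prevalences
  if (any(prev < 0 | prev > 1))
    lirads_abort("prevalences must lie in [0, 1]", "lirads_config_error")

  set.seed(rng_seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    has <- stats::rbinom(4, 1, prev[c("aphe", "washout", "capsule", "threshold_growth")]) == 1
    names(has) <- c("aphe", "washout", "capsule", "threshold_growth")
    delta <- if (has[["aphe"]]) stats::runif(1, 10, 50) else stats::runif(1, -20, -5)
    if (has[["washout"]]) {
      par_del <- stats::runif(1, 1.05, 1.30)
      par_pv <- stats::runif(1, 0.90, 1.30)
    } else {
      par_del <- stats::runif(1, 0.85, 0.98)
      par_pv <- stats::runif(1, 0.85, 0.98)
    }
    a <- stats::runif(1, lesion_semiaxis_range_mm[1], lesion_semiaxis_range_mm[2])
    radii <- c(a, a * stats::runif(1, 0.85, 1), a * stats::runif(1, 0.85, 1))
    prior <- NULL
    if (has[["threshold_growth"]]) {
      # prior small enough that current size exceeds it by >= 50%, recent exam
      prior <- list(diameter_mm = (2 * a) / stats::runif(1, 1.55, 2.0),
                    days_before = round(stats::runif(1, 60, 150)))
    } else if (stats::runif(1) < 0.5) {
      # stable prior or one outside the 6-month window
      recent <- stats::runif(1) < 0.5
      prior <- list(diameter_mm = (2 * a) / stats::runif(1, 1.0, 1.2),
                    days_before = if (recent) round(stats::runif(1, 60, 150))
                                  else round(stats::runif(1, 200, 400)))
    }
    seed_i <- sample.int(.Machine$integer.max, 1)
    cfg <- phantom_config(
      volume_shape = volume_shape, spacing_mm = spacing_mm,
      lesion_radii_mm = radii, aphe_delta_hu = delta,
      par_pv = par_pv, par_del = par_del,
      capsule = has[["capsule"]],
      noise_sigma_hu = noise_sigma_hu, rng_seed = seed_i,
      prior_exam = prior
    )
    out[[i]] <- generate_phantom(cfg)
  }
  out
}

#' Write a phantom study to disk
#'
#' Volumes go out via [write_study]; the ground truth (without the voxel
#' mask) is written as `<prefix>_truth.json`.
#'
#' @param phantom result of [generate_phantom].
#' @param prefix output path prefix.
#' @export
write_phantom <- function(phantom, prefix) {
  write_study(phantom$study, prefix)
  tr <- phantom$truth
  tr$lesion_mask <- NULL; tr$capsule_rim_mask <- NULL
  jsonlite::write_json(unclass(tr), paste0(prefix, "_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
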