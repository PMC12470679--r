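# Lesion measurements: densities, size, first-order histogram features.

# Maximum axial diameter: the longest point-to-point distance between voxel
# centres within any single axial slice (third axis), plus one in-plane
# voxel extent so a single voxel has nonzero size. Matches the clinical
# caliper convention (in-plane, not 3D). Returns the slice and direction so
# the perpendicular diameter can be taken on the same slice.
mask_max_axial_diameter <- function(mask, spacing_mm) {
  ext <- mean(spacing_mm[1:2])
  best <- list(diameter_mm = ext, slice = NA_integer_, dir = c(1, 0),
               p1 = NULL, p2 = NULL)
  zs <- which(apply(mask, 3, any))
  for (z in zs) {
    ij <- which(mask[, , z, drop = FALSE][, , 1], arr.ind = TRUE)
    pts <- cbind((ij[, 1] - 1) * spacing_mm[1], (ij[, 2] - 1) * spacing_mm[2])
    if (nrow(pts) > 3) pts <- pts[grDevices::chull(pts), , drop = FALSE]
    if (nrow(pts) == 1) { dmax <- 0; i1 <- i2 <- 1 }
    else {
      dd <- as.matrix(stats::dist(pts))
      w <- which.max(dd)
      i1 <- (w - 1) %% nrow(dd) + 1; i2 <- (w - 1) %/% nrow(dd) + 1
      dmax <- dd[w]
    }
    if (dmax + ext > best$diameter_mm || is.na(best$slice)) {
      best <- list(diameter_mm = dmax + ext, slice = z,
                   dir = if (dmax > 0) (pts[i2, ] - pts[i1, ]) / dmax else c(1, 0),
                   p1 = pts[i1, ], p2 = pts[i2, ])
    }
  }
  best
}

# In-plane diameter perpendicular to `dir` on slice `z`.
mask_perp_diameter <- function(mask, spacing_mm, z, dir) {
  ij <- which(mask[, , z, drop = FALSE][, , 1], arr.ind = TRUE)
  pts <- cbind((ij[, 1] - 1) * spacing_mm[1], (ij[, 2] - 1) * spacing_mm[2])
  v <- c(-dir[2], dir[1])
  proj <- pts %*% v
  diff(range(proj)) + mean(spacing_mm[1:2])
}

#' Measure a segmented lesion on one phase
#'
#' Computes the mean and SD of the lesion HU, the volume in mL, the maximum
#' axial diameter and the perpendicular in-plane diameter on the same slice
#' (both in mm, voxel extent included), and first-order histogram texture
#' features (min, max, median, skewness, kurtosis, and the Shannon entropy
#' of a 64-bin HU histogram, in bits).
#'
#' @param mask a [lesion_mask] on the same grid as `image`.
#' @param image a [phase_image].
#' @return an object of class `lesion_measurement` (a list).
#' @export
lesion_metrics <- function(mask, image) {
  stopifnot(inherits(mask, "lesion_mask"), inherits(image, "phase_image"))
  if (!identical(dim(mask$mask), dim(image$hu)))
    lirads_abort("mask grid does not match the image", "lirads_format_error")
  m <- mask$mask
  sp <- image$spacing_mm
  vals <- image$hu[m]
  dia <- mask_max_axial_diameter(m, sp)
  perp <- mask_perp_diameter(m, sp, dia$slice, dia$dir)

  h <- if (diff(range(vals)) > 0) {
    counts <- tabulate(cut(vals, breaks = 64, labels = FALSE), nbins = 64)
    p <- counts[counts > 0] / length(vals)
    -sum(p * log2(p))
  } else 0

  structure(list(
    phase = image$phase,
    n_voxels = sum(m),
    mean_hu = mean(vals),
    sd_hu = stats::sd(vals),
    volume_ml = sum(m) * prod(sp) / 1000,
    max_axial_diameter_mm = dia$diameter_mm,
    perp_diameter_mm = perp,
    slice = dia$slice,
    texture = c(min = min(vals), max = max(vals), median = stats::median(vals),
                skewness = if (length(vals) > 1) e1071::skewness(vals) else 0,
                kurtosis = if (length(vals) > 1) e1071::kurtosis(vals) else 0,
                entropy = h)
  ), class = "lesion_measurement")
}

#' @export
print.lesion_measurement <- function(x, ...) {
  cat(sprintf("<lesion_measurement> %s: %.1f HU (SD %.1f), %.2f mL, %.1f x %.1f mm\n",
              x$phase, x$mean_hu, x$sd_hu, x$volume_ml,
              x$max_axial_diameter_mm, x$perp_diameter_mm))
  invisible(x)
}

#' Measure a lesion on every phase of a study
#'
#' Applies one mask (identical geometry across co-registered phases) to each
#' phase and collects the measurements.
#'
#' @param study named list of [phase_image] objects.
#' @param mask a [lesion_mask].
#' @return named list of `lesion_measurement` objects, one per phase.
#' @export
measure_study <- function(study, mask) {
  lapply(study, function(p) lesion_metrics(mask, p))
}

#' Dice similarity between two masks
#'
#' @param a,b logical 3D arrays (or [lesion_mask] objects) on the same grid.
#' @return the Dice coefficient in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "lesion_mask")) a <- a$mask
  if (inherits(b, "lesion_mask")) b <- b$mask
  2 * sum(a & b) / (sum(a) + sum(b))
}
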