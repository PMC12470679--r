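# Sphere-seeded semi-automatic 3D lesion segmentation.
#
# The clinical workflow: the reader clicks the lesion centre and drags a
# sphere around it; the sphere both initialises and bounds the segmentation.
# The algorithm here is fixed and documented: (1) estimate the seed HU mean m
# and SD s in a small ball around the centre; (2) grow a 26-connected region
# from the centre accepting voxels with HU in [m - k*s, m + k*s], confined to
# the seed sphere; (3) morphological closing (1-voxel ball), hole filling,
# keep the largest connected component. Deterministic. Suited to homogeneous,
# well-defined lesions; inhomogeneous lesions with blurred contours can fail
# (small grown region), which is reported as a segmentation-failure error.

#' Construct a sphere seed
#'
#' @param center_mm physical coordinates (mm) of the lesion centre.
#' @param radius_mm sphere radius in mm (> 0); the sphere must intersect the
#'   volume it is used on.
#' @param phase optional label of the phase the seed was placed on.
#' @return an object of class `sphere_seed`.
#' @export
sphere_seed <- function(center_mm, radius_mm, phase = "arterial") {
  if (length(center_mm) != 3L || any(!is.finite(center_mm)))
    lirads_abort("center_mm must be 3 finite coordinates", "lirads_config_error")
  if (length(radius_mm) != 1L || !is.finite(radius_mm) || radius_mm <= 0)
    lirads_abort("radius_mm must be a positive length", "lirads_config_error")
  structure(list(center_mm = as.numeric(center_mm), radius_mm = radius_mm,
                 phase = phase),
            class = "sphere_seed")
}

#' Construct a lesion mask
#'
#' Wraps a boolean voxel mask on the grid of a [phase_image], with
#' provenance. Manual overrides and edited masks enter the pipeline through
#' this constructor.
#'
#' @param mask logical 3D array with at least one `TRUE` voxel.
#' @param provenance one of `"automatic"`, `"manually_edited"`,
#'   `"manual_override"`.
#' @param seed the [sphere_seed] that produced the mask, if any.
#' @return an object of class `lesion_mask`.
#' @export
lesion_mask <- function(mask, provenance = "manual_override", seed = NULL) {
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    lirads_abort("mask must be a logical 3D array", "lirads_format_error")
  if (!any(mask))
    lirads_abort("mask has no voxels", "lirads_format_error")
  provenance <- match.arg(provenance,
                          c("automatic", "manually_edited", "manual_override"))
  structure(list(mask = mask, provenance = provenance, seed = seed),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %d voxels (%s)\n", sum(x$mask), x$provenance))
  invisible(x)
}

#' Segment a lesion from a sphere seed
#'
#' @param image a [phase_image].
#' @param seed a [sphere_seed]; its centre must lie inside the volume.
#' @param k half-width of the HU acceptance band in units of the seed SD
#'   (default 2.5). Larger k grows into lower-contrast surroundings; masks
#'   are nested in k.
#' @param min_voxels grown regions smaller than this raise a
#'   segmentation-failure error (default 10).
#' @return a [lesion_mask] with provenance `"automatic"`. The mask is always
#'   contained in the seed sphere dilated by one voxel.
#' @export
segment_sphere_seed <- function(image, seed, k = 2.5, min_voxels = 10L) {
  stopifnot(inherits(image, "phase_image"), inherits(seed, "sphere_seed"))
  d <- dim(image$hu); sp <- image$spacing_mm
  cvox <- round(mm_to_voxel(seed$center_mm, sp))
  if (any(cvox < 1) || any(cvox > d))
    lirads_abort("seed centre lies outside the volume", "lirads_config_error")

  # crop to the sphere's bounding box (+2 voxels) for speed
  lo <- pmax(1, floor(mm_to_voxel(seed$center_mm - seed$radius_mm, sp)) - 2)
  hi <- pmin(d, ceiling(mm_to_voxel(seed$center_mm + seed$radius_mm, sp)) + 2)
  sub <- image$hu[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  subd <- dim(sub)
  center_sub <- seed$center_mm - (lo - 1) * sp

  d2 <- dist2_grid(subd, sp, center_sub)
  sphere <- d2 <= seed$radius_mm^2

  r0 <- min(5, seed$radius_mm / 2)
  stat_ball <- d2 <= r0^2
  vals <- sub[stat_ball]
  m <- mean(vals)
  s <- if (length(vals) > 1) stats::sd(vals) else 0
  tol <- 1e-6
  accept <- sphere & sub >= (m - k * s - tol) & sub <= (m + k * s + tol)

  seeds <- which(stat_ball & accept)
  if (!length(seeds))
    lirads_abort("no seed voxel falls inside the HU acceptance band",
                 "lirads_segmentation_error")
  grown <- flood3d(accept, seeds, connectivity = 26)
  grown <- close3d(grown)
  grown <- fill_holes3d(grown)
  grown <- grown & dilate3d(sphere)   # confinement: sphere dilated by 1 voxel
  grown <- largest_component3d(grown)

  if (sum(grown) < min_voxels)
    lirads_abort(sprintf(
      "segmentation failed: grown region has %d voxels (< %d); lesion margins may be blurred or inhomogeneous",
      sum(grown), min_voxels), "lirads_segmentation_error")

  full <- array(FALSE, d)
  full[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- grown
  lesion_mask(full, provenance = "automatic", seed = seed)
}

#' Write / read a lesion mask as NIfTI
#'
#' @param mask a [lesion_mask].
#' @param path NIfTI file path.
#' @param spacing_mm voxel spacing to stamp into the header.
#' @export
write_mask <- function(mask, path, spacing_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.integer(mask$mask), dim(mask$mask)))
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  lesion_mask(array(as.numeric(img) > 0.5, dim(img)), provenance = "manual_override")
}
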