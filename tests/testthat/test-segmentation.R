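test_that("noise-free ellipsoid is segmented exactly from a loose seed", {
  cfg <- tiny_config(noise_sigma_hu = 0)
  ph <- generate_phantom(cfg)
  seed <- sphere_seed(cfg$lesion_center_mm, 1.5 * max(cfg$lesion_radii_mm))
  mk <- segment_sphere_seed(ph$study$arterial, seed)
  # oracle: analytic ellipsoid rasterization, computed point by point
  expect_identical(mk$mask, rasterize_ellipsoid(cfg))
  expect_identical(mk$provenance, "automatic")
})

test_that("a seed in a uniform field accepts the whole sphere", {
  img <- phase_image(array(60, c(24, 24, 24)), c(1, 1, 1), "native")
  seed <- sphere_seed(c(11.5, 11.5, 11.5), 6)
  mk <- segment_sphere_seed(img, seed)
  sphere <- with(list(), {
    g <- expand.grid(x = 0:23, y = 0:23, z = 0:23)
    array(sqrt((g$x - 11.5)^2 + (g$y - 11.5)^2 + (g$z - 11.5)^2) <= 6, c(24, 24, 24))
  })
  expect_true(all(mk$mask[sphere]))          # sphere fully accepted
  # confinement: nothing beyond the 1-voxel-dilated sphere
  dil <- sphere
  for (d in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
    sh <- array(FALSE, dim(sphere))
    idx <- pmin(pmax(which(sphere, arr.ind = TRUE) +
                     matrix(d, sum(sphere), 3, byrow = TRUE), 1), 24)
    sh[idx] <- TRUE
    dil <- dil | sh
  }
  expect_false(any(mk$mask & !dil))
})

test_that("noisy phantom segmentation overlaps the truth (Dice >= 0.80)", {
  cfg <- phantom_config(noise_sigma_hu = 10, rng_seed = 42)  # contrast 25 HU
  ph <- generate_phantom(cfg)
  seed <- sphere_seed(cfg$lesion_center_mm, max(cfg$lesion_radii_mm))
  mk <- segment_sphere_seed(ph$study$arterial, seed)
  expect_gte(dice_coefficient(mk$mask, ph$truth$lesion_mask), 0.80)
})

test_that("masks are nested in the acceptance band width k", {
  cfg <- tiny_config(noise_sigma_hu = 8, rng_seed = 11)
  ph <- generate_phantom(cfg)
  seed <- sphere_seed(cfg$lesion_center_mm, max(cfg$lesion_radii_mm))
  masks <- lapply(c(1.5, 2.5, 3.5), function(k)
    segment_sphere_seed(ph$study$arterial, seed, k = k)$mask)
  expect_false(any(masks[[1]] & !masks[[2]]))
  expect_false(any(masks[[2]] & !masks[[3]]))
})

test_that("a tiny grown region raises a segmentation failure", {
  # a 7-voxel cross of lesion HU in flat background: the band admits only
  # those voxels, below the minimum region size
  hu <- array(0, c(24, 24, 24))
  hu[12, 12, 12] <- 100
  hu[c(11, 13), 12, 12] <- 100; hu[12, c(11, 13), 12] <- 100
  hu[12, 12, c(11, 13)] <- 100
  img <- phase_image(hu, c(1, 1, 1), "arterial")
  seed <- sphere_seed(c(11, 11, 11), 2)   # stats ball = exactly the cross
  expect_error(segment_sphere_seed(img, seed),
               class = "lirads_segmentation_error")
})

test_that("segmentation failures surface as errors, not masks", {
  expect_error(lesion_mask(array(FALSE, c(4, 4, 4))), class = "lirads_format_error")
  img <- phase_image(array(0, c(8, 8, 8)), c(1, 1, 1), "native")
  expect_error(segment_sphere_seed(img, sphere_seed(c(50, 0, 0), 3)),
               class = "lirads_config_error")
})

test_that("lesion metrics match analytic values on noise-free shapes", {
  # single voxel: volume 0.001 mL, diameter 1 mm by the voxel-extent convention
  img <- phase_image(array(50, c(8, 8, 8)), c(1, 1, 1), "native")
  m <- array(FALSE, c(8, 8, 8)); m[4, 4, 4] <- TRUE
  met <- lesion_metrics(lesion_mask(m), img)
  expect_equal(met$volume_ml, 0.001)
  expect_equal(met$max_axial_diameter_mm, 1)
  expect_equal(met$perp_diameter_mm, 1)

  # sphere radius 10 mm: diameter 20 +- 1 mm, volume within one voxel shell
  cfg <- phantom_config(volume_shape = c(40, 40, 40),
                        lesion_radii_mm = c(10, 10, 10), noise_sigma_hu = 0)
  ph <- generate_phantom(cfg)
  met <- lesion_metrics(lesion_mask(ph$truth$lesion_mask), ph$study$arterial)
  expect_lt(abs(met$max_axial_diameter_mm - 20), 1)
  v_analytic <- 4 / 3 * pi * 10^3 / 1000
  shell <- 4 * pi * 10^2 * 1 / 1000          # surface area x voxel size
  expect_lt(abs(met$volume_ml - v_analytic), shell)
  # exact arterial HU and degenerate texture on a constant lesion
  expect_equal(met$mean_hu, 100)
  expect_equal(unname(met$texture["entropy"]), 0)
})

test_that("ellipsoid metrics: per-axis diameters follow the geometry", {
  cfg <- default_noisefree()                  # semi-axes 16, 14, 12 mm
  ph <- generate_phantom(cfg)
  met <- lesion_metrics(lesion_mask(ph$truth$lesion_mask), ph$study$portal_venous)
  expect_lt(abs(met$max_axial_diameter_mm - 32), sqrt(2))   # within a voxel diagonal
  expect_lt(abs(met$perp_diameter_mm - 28), sqrt(2))
  v_analytic <- 4 / 3 * pi * 16 * 14 * 12 / 1000
  shell <- 4 * pi * 14^2 * 1 / 1000
  expect_lt(abs(met$volume_ml - v_analytic), shell)
})

test_that("first-order texture features track the HU distribution", {
  cfg <- phantom_config(noise_sigma_hu = 10, rng_seed = 21)
  ph <- generate_phantom(cfg)
  met <- lesion_metrics(lesion_mask(ph$truth$lesion_mask), ph$study$arterial)
  tx <- met$texture
  expect_lt(abs(tx[["median"]] - 100), 1)
  expect_lt(abs(tx[["skewness"]]), 0.1)      # Gaussian noise: symmetric
  expect_lt(abs(tx[["kurtosis"]]), 0.2)      # excess kurtosis near 0
  expect_gt(tx[["entropy"]], 2)              # far from degenerate
  expect_true(tx[["min"]] < 100 && tx[["max"]] > 100)
})

test_that("masks round-trip through NIfTI", {
  cfg <- tiny_config(noise_sigma_hu = 0)
  ph <- generate_phantom(cfg)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(lesion_mask(ph$truth$lesion_mask), f, cfg$spacing_mm)
  back <- read_mask(f)
  expect_identical(back$mask, ph$truth$lesion_mask)
  expect_identical(back$provenance, "manual_override")
})

test_that("per-phase segmentation yields phase-dependent diameters", {
  # with noise and phase-dependent contrast (capsule conspicuity differs by
  # phase), independently segmented phases measure slightly different
  # calipers on the same lesion, as clinical per-phase measurements do
  cfg <- phantom_config(noise_sigma_hu = 10, rng_seed = 13, capsule = TRUE)
  ph <- generate_phantom(cfg)
  seed <- sphere_seed(cfg$lesion_center_mm, max(cfg$lesion_radii_mm))
  diams <- vapply(ph$study, function(p) {
    mk <- segment_sphere_seed(p, seed)
    lesion_metrics(mk, p)$max_axial_diameter_mm
  }, 0)
  expect_gt(max(diams) - min(diams), 0)       # variation across phases
  expect_true(all(abs(diams - 32) < 6))       # all near the true 32 mm caliper
})
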