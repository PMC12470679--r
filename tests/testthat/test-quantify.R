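test_that("APHE follows the strict sign of the arterial HU difference", {
  # the cohort's single negative case: lesion 1.4 HU below liver
  r <- compute_aphe(80 - 1.4, 80)
  expect_equal(r$delta, -1.4)
  expect_identical(r$aphe, "no")
  # strict-positivity boundary: isodense is not hyperenhancement
  expect_identical(compute_aphe(80, 80)$aphe, "no")
  # the positive range seen clinically (0.9 to 78.3 HU above liver)
  for (d in c(0.9, 5, 78.3))
    expect_identical(compute_aphe(80 + d, 80)$aphe, "yes")
  # missing arterial phase: not evaluable, never "no"
  expect_identical(compute_aphe(NA, 80)$aphe, "not_evaluable")
})

test_that("APHE delta is antisymmetric in lesion and liver", {
  for (pair in list(c(100, 80), c(55, 62.5), c(70, 70)))
    expect_equal(compute_aphe(pair[1], pair[2])$delta,
                 -compute_aphe(pair[2], pair[1])$delta)
})

test_that("PAR is the liver/lesion ratio, scale-equivariant, guarded at 0", {
  expect_equal(compute_par(100, 100), 1)
  expect_equal(compute_par(113, 100), 1.13)   # above the 113% visual-washout guide
  expect_equal(compute_par(90, 120), 0.75)
  for (c_scale in c(0.5, 2, 10))
    expect_equal(compute_par(113 * c_scale, 100 * c_scale), 1.13)
  expect_error(compute_par(100, 0), class = "lirads_par_error")
  expect_error(compute_par(100, -5), class = "lirads_par_error")
})

test_that("washout takes the higher venous PAR, strictly above 1", {
  r <- assess_washout(par_pv = 0.98, par_del = 1.05)
  expect_identical(r$washout, "yes")
  expect_identical(r$phase_used, "delayed")
  expect_equal(r$par_used, 1.05)
  # boundary: exactly isodense in both phases is no washout
  expect_identical(assess_washout(1.0, 1.0)$washout, "no")
  # single available phase decides alone
  r2 <- assess_washout(par_del = 1.2)
  expect_identical(r2$washout, "yes")
  expect_identical(r2$phase_used, "delayed")
  # neither venous phase: not evaluable
  expect_identical(assess_washout()$washout, "not_evaluable")
})

test_that("threshold growth is >= 50% within 183 days, else 'no'", {
  r <- assess_threshold_growth(15, 10, 120)
  expect_identical(r$growth, "yes")          # boundary: exactly 50%
  expect_equal(r$fraction, 0.5)
  expect_identical(assess_threshold_growth(14.9, 10, 120)$growth, "no")
  expect_identical(assess_threshold_growth(30, 10, 184)$growth, "no")
  expect_identical(assess_threshold_growth(15, 10, 183)$growth, "yes")
  r2 <- assess_threshold_growth(30)
  expect_identical(r2$growth, "no")          # no prior exam
  expect_true(is.na(r2$fraction))
  expect_error(assess_threshold_growth(-3, 10, 30), class = "lirads_format_error")
  expect_error(assess_threshold_growth(15, -10, 30), class = "lirads_format_error")
})

test_that("size selection returns the chosen phase and warns on arterial", {
  diams <- c(native = 29.1, arterial = 27.9, portal_venous = 28.9, delayed = 30.8)
  expect_equal(select_size(diams, "native")$size_mm, 29.1)
  expect_warning(r <- select_size(diams, "arterial"),
                 class = "lirads_size_phase_warning")
  expect_equal(r$size_mm, 27.9)
  expect_equal(select_size(c(delayed = 30.8), "delayed")$size_mm, 30.8)
  expect_error(select_size(diams[1:2], "delayed"), class = "lirads_format_error")
})

test_that("background liver averages the two lobe ROIs per phase", {
  cfg <- default_noisefree()
  ph <- generate_phantom(cfg)
  bg <- background_liver(ph$study)
  expect_equal(unname(bg[c("native", "arterial", "portal_venous", "delayed")]),
               c(55, 75, 110, 100))
  expect_error(background_liver(ph$study, roi_centers_mm = list(c(0, 0, 0))),
               class = "lirads_config_error")
  expect_error(background_liver(ph$study,
                                roi_centers_mm = list(c(0, 0, 0), c(1e4, 0, 0))),
               class = "lirads_config_error")
})

test_that("noise-free phantoms recover every flag over the enhancement grid", {
  for (delta in seq(-20, 40, by = 10)) {
    for (par in c(0.8, 0.9, 1.0, 1.1, 1.2, 1.3)) {
      cfg <- tiny_config(noise_sigma_hu = 0, aphe_delta_hu = delta,
                         par_pv = par, par_del = par)
      ph <- generate_phantom(cfg)
      mk <- lesion_mask(ph$truth$lesion_mask)
      hu_lesion <- vapply(ph$study, function(p) mean(p$hu[mk$mask]), 0)
      bg <- background_liver(ph$study)
      mf <- major_features(hu_lesion, bg,
                           diam_by_phase = c(portal_venous = 12),
                           chosen_phase = "portal_venous")
      expect_identical(mf$aphe, if (ph$truth$expected_aphe) "yes" else "no")
      expect_identical(mf$washout, if (ph$truth$expected_washout) "yes" else "no")
    }
  }
})

test_that("major_features propagates missing phases as not-evaluable", {
  mf <- major_features(hu_lesion = c(pv = 100, del = 90),
                       hu_liver = c(pv = 110, del = 100),
                       diam_by_phase = c(pv = 22), chosen_phase = "portal_venous")
  expect_identical(mf$aphe, "not_evaluable")
  expect_identical(mf$washout, "yes")
  mf2 <- major_features(hu_lesion = c(art = 100), hu_liver = c(art = 80),
                        diam_by_phase = c(art = 22), chosen_phase = "arterial") |>
    suppressWarnings()
  expect_identical(mf2$aphe, "yes")
  expect_identical(mf2$washout, "not_evaluable")
})
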