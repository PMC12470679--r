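# Exhaustive checks of the v2018 CT diagnostic-table engine.

mf_stub <- function(aphe, size_mm, capsule = "no", washout = "no",
                    growth = "no") {
  list(aphe = aphe, size_mm = size_mm, capsule = capsule, washout = washout,
       threshold_growth = growth)
}

feature_combos <- expand.grid(capsule = c("no", "yes"), washout = c("no", "yes"),
                              growth = c("no", "yes"), stringsAsFactors = FALSE)

# Hand-written expected map of the v2018 CT base table, cell by cell.
expected_base <- function(aphe, size_mm, capsule, washout, growth) {
  n <- sum(c(capsule, washout, growth) == "yes")
  if (aphe == "no") {
    if (size_mm < 20) c("LR-3", "LR-3", "LR-4", "LR-4")[n + 1]
    else c("LR-3", "LR-4", "LR-4", "LR-4")[n + 1]
  } else {
    if (size_mm < 10) {
      if (n == 0) "LR-3" else "LR-4"
    } else if (size_mm < 20) {
      if (n == 0) "LR-3"
      else if (n == 1 && capsule == "yes") "LR-4"   # capsule alone
      else "LR-5"
    } else {
      if (n == 0) "LR-4" else "LR-5"
    }
  }
}

test_that("every base-table cell matches the hand-written expected map", {
  for (aphe in c("no", "yes")) for (size in c(8, 15, 25)) {
    for (i in seq_len(nrow(feature_combos))) {
      fc <- feature_combos[i, ]
      res <- classify_lirads(mf_stub(aphe, size, fc$capsule, fc$washout, fc$growth))
      expect_identical(
        res$base_category,
        expected_base(aphe, size, fc$capsule, fc$washout, fc$growth),
        label = sprintf("APHE=%s size=%g capsule=%s washout=%s growth=%s -> %s",
                        aphe, size, fc$capsule, fc$washout, fc$growth,
                        res$base_category))
      expect_identical(res$category, res$base_category)  # no ancillary input
      expect_gt(length(res$rationale), 0)
    }
  }
})

test_that("the downgraded worked case lands at LR-3", {
  # APHE lost arithmetically and the best-phase size fell below 20 mm,
  # with one additional feature present
  res <- classify_lirads(mf_stub("no", 18, washout = "yes"))
  expect_identical(res$category, "LR-3")
  # the classical LR-5 definition: APHE, >= 10 mm (here 25), washout
  expect_identical(classify_lirads(mf_stub("yes", 25, washout = "yes"))$category,
                   "LR-5")
  # APHE present, 25 mm, no additional feature: LR-4
  expect_identical(classify_lirads(mf_stub("yes", 25))$category, "LR-4")
})

test_that("base category is monotone in features, size bin and APHE", {
  lv <- function(x) match(x, c("LR-1", "LR-2", "LR-3", "LR-4", "LR-5"))
  sizes <- c(8, 15, 25)
  for (aphe in c("no", "yes")) for (si in sizes) {
    for (i in seq_len(nrow(feature_combos))) {
      fc <- feature_combos[i, ]
      base <- lv(classify_lirads(mf_stub(aphe, si, fc$capsule, fc$washout,
                                         fc$growth))$base_category)
      # turning any absent feature on never lowers the category
      for (f in c("capsule", "washout", "growth")) {
        if (fc[[f]] == "no") {
          fc2 <- fc; fc2[[f]] <- "yes"
          expect_gte(lv(classify_lirads(mf_stub(aphe, si, fc2$capsule, fc2$washout,
                                                fc2$growth))$base_category), base)
        }
      }
      # increasing the size bin never lowers the category
      for (s2 in sizes[sizes > si])
        expect_gte(lv(classify_lirads(mf_stub(aphe, s2, fc$capsule, fc$washout,
                                              fc$growth))$base_category), base)
      # turning APHE on never lowers the category
      if (aphe == "no")
        expect_gte(lv(classify_lirads(mf_stub("yes", si, fc$capsule, fc$washout,
                                              fc$growth))$base_category), base)
    }
  }
})

test_that("ancillary adjustment moves one step and never upgrades to LR-5", {
  mal <- ancillary_features(favoring_malignancy = c(subthreshold_growth = "yes"))
  ben <- ancillary_features(favoring_benignity = c(size_stability_2y = "yes"))
  both <- ancillary_features(favoring_malignancy = c(subthreshold_growth = "yes"),
                             favoring_benignity = c(size_stability_2y = "yes"))
  lv <- function(x) match(x, c("LR-1", "LR-2", "LR-3", "LR-4", "LR-5"))
  for (aphe in c("no", "yes")) for (size in c(8, 15, 25)) {
    for (i in seq_len(nrow(feature_combos))) {
      fc <- feature_combos[i, ]
      stub <- mf_stub(aphe, size, fc$capsule, fc$washout, fc$growth)
      base <- classify_lirads(stub)$base_category
      up <- classify_lirads(stub, mal)$category
      down <- classify_lirads(stub, ben)$category
      none <- classify_lirads(stub, both)$category
      expect_identical(none, base)
      expect_lte(abs(lv(up) - lv(base)), 1)
      expect_lte(abs(lv(down) - lv(base)), 1)
      expect_gte(lv(up), lv(base)); expect_lte(lv(down), lv(base))
      if (base != "LR-5") expect_true(up != "LR-5")   # upgrade capped at LR-4
    }
  }
  # not-evaluable ancillary entries never adjust
  ne <- ancillary_features(favoring_malignancy = c(x = "not_evaluable"))
  expect_identical(classify_lirads(mf_stub("yes", 25), ne)$category, "LR-4")
})

test_that("not-evaluable major features count as absent; bad inputs error", {
  res <- classify_lirads(mf_stub("yes", 25, washout = "not_evaluable"))
  expect_identical(res$category, "LR-4")
  expect_match(paste(res$rationale, collapse = " "), "not-evaluable")
  expect_error(classify_lirads(mf_stub("not_evaluable", 25)),
               class = "lirads_classification_error")
  expect_error(classify_lirads(mf_stub("yes", -1)),
               class = "lirads_classification_error")
  # explicit benign diagnosis is the only path to LR-1/LR-2
  expect_identical(classify_lirads(mf_stub("yes", 25),
                                   benign_diagnosis = "definite")$category, "LR-1")
  expect_identical(classify_lirads(mf_stub("yes", 25),
                                   benign_diagnosis = "probable")$category, "LR-2")
})

test_that("batch classification conserves counts and collects errors", {
  recs <- rbind(
    measurement_record("A", hu_lesion = c(art = 100, pv = 100, del = 87),
                       hu_liver = c(art = 75, pv = 110, del = 100),
                       diam = c(art = 25, pv = 24, del = 24), capsule = "no"),
    measurement_record("B", hu_lesion = c(art = 70, pv = 100, del = 100),
                       hu_liver = c(art = 75, pv = 95, del = 98),
                       diam = c(art = 15, pv = 15, del = 15), capsule = "no"),
    measurement_record("C", hu_lesion = c(pv = 100),  # APHE not evaluable
                       hu_liver = c(pv = 110), diam = c(pv = 12), capsule = "no")
  )
  out <- batch_classify(recs, chosen_phase = "pv")
  expect_length(out$errors, 1)
  expect_named(out$errors, "C")
  expect_equal(sum(out$histogram$count), 2)
  expect_identical(out$results$A$category, "LR-5")
  expect_identical(out$results$B$category, "LR-3")
  empty <- batch_classify(recs[0, ])
  expect_equal(nrow(empty$histogram), 0)
})
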