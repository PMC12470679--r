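# LI-RADS v2018 CT diagnostic-table engine.
#
# Base category from APHE status, size bin and the count of additional major
# features (enhancing capsule, non-peripheral washout, threshold growth),
# per the v2018 CT/MRI diagnostic table; ancillary features may shift the
# category by one step, with upgrades capped at LR-4 (never to LR-5).

LR_LEVELS <- c("LR-1", "LR-2", "LR-3", "LR-4", "LR-5")

#' Ancillary feature lists
#'
#' Minor imaging features favouring malignancy (e.g. subthreshold growth,
#' non-enhancing capsule, blood products in mass) or benignity (e.g. size
#' stability over 2 years, size reduction). Each entry is a tristate token;
#' only `"yes"` entries count.
#'
#' @param favoring_malignancy,favoring_benignity named character vectors of
#'   tristate tokens.
#' @return an object of class `ancillary_features`.
#' @export
ancillary_features <- function(favoring_malignancy = character(0),
                               favoring_benignity = character(0)) {
  for (x in favoring_malignancy) as_tristate(x, "ancillary feature")
  for (x in favoring_benignity) as_tristate(x, "ancillary feature")
  structure(list(favoring_malignancy = favoring_malignancy,
                 favoring_benignity = favoring_benignity),
            class = "ancillary_features")
}

# v2018 base table. aphe: "no"/"yes" (nonrim); bin: "<10"/"10-19"/">=20";
# n_feat: 0..3; one_is_capsule_only: for the nonrim-APHE 10-19 mm / one-
# feature cell, capsule alone gives LR-4 while washout or threshold growth
# gives LR-5.
lirads_base_category <- function(aphe, bin, n_feat, capsule_only = FALSE) {
  if (aphe == "no") {
    if (bin %in% c("<10", "10-19")) {
      if (n_feat >= 2) "LR-4" else "LR-3"
    } else {
      if (n_feat == 0) "LR-3" else "LR-4"
    }
  } else {
    if (bin == "<10") {
      if (n_feat == 0) "LR-3" else "LR-4"
    } else if (bin == "10-19") {
      if (n_feat == 0) "LR-3"
      else if (n_feat == 1) { if (capsule_only) "LR-4" else "LR-5" }
      else "LR-5"
    } else {
      if (n_feat == 0) "LR-4" else "LR-5"
    }
  }
}

#' Classify a lesion with the LI-RADS v2018 diagnostic table
#'
#' Computes the base category from APHE, size and the additional major
#' features, then applies the ancillary adjustment: one or more
#' malignancy-favouring features (and none favouring benignity) upgrade by
#' one category but never to LR-5; benignity-favouring features downgrade by
#' one; both present cancel out. Not-evaluable major features count as
#' absent (a category should not rise on unevaluable evidence).
#'
#' @param major a [major_features] result (or a list with fields `aphe`,
#'   `size_mm`, `capsule`, `washout`, `threshold_growth`).
#' @param ancillary an [ancillary_features] object, or `NULL`.
#' @param benign_diagnosis `"none"` (default), `"probable"` (LR-2) or
#'   `"definite"` (LR-1): explicit benign-diagnosis input, the only path to
#'   LR-1/LR-2.
#' @return an object of class `lirads_result` with `category`,
#'   `base_category` and an ordered `rationale` trace.
#' @export
classify_lirads <- function(major, ancillary = NULL,
                            benign_diagnosis = c("none", "probable", "definite")) {
  benign_diagnosis <- match.arg(benign_diagnosis)
  if (benign_diagnosis != "none") {
    cat_b <- if (benign_diagnosis == "definite") "LR-1" else "LR-2"
    return(structure(list(
      category = cat_b, base_category = cat_b,
      rationale = sprintf("explicit %s benign diagnosis -> %s", benign_diagnosis, cat_b),
      n_features = NA_integer_
    ), class = "lirads_result"))
  }

  if (is.null(major$aphe) || major$aphe == "not_evaluable")
    lirads_abort("APHE is not evaluable: categorize manually", "lirads_classification_error")
  if (is.null(major$size_mm) || is.na(major$size_mm) || major$size_mm < 0)
    lirads_abort("size is missing or negative", "lirads_classification_error")

  bin <- size_bin(major$size_mm)
  feats <- c(capsule = identical(major$capsule, "yes"),
             washout = identical(major$washout, "yes"),
             threshold_growth = identical(major$threshold_growth, "yes"))
  n <- sum(feats)
  capsule_only <- n == 1 && feats[["capsule"]]
  base <- lirads_base_category(major$aphe, bin, n, capsule_only)

  rationale <- c(sprintf(
    "base table: APHE %s, size %.1f mm (bin %s), %d additional feature(s)%s -> %s",
    major$aphe, major$size_mm, bin, n,
    if (n > 0) sprintf(" [%s]", paste(names(feats)[feats], collapse = ", ")) else "",
    base))
  ne <- c(major$capsule, major$washout, major$threshold_growth) == "not_evaluable"
  if (any(ne))
    rationale <- c(rationale, sprintf(
      "not-evaluable feature(s) counted as absent: %s",
      paste(c("capsule", "washout", "threshold_growth")[ne], collapse = ", ")))
  if (major$aphe == "yes" && bin == "10-19" && capsule_only)
    rationale <- c(rationale,
      "10-19 mm with capsule as the only additional feature: LR-4 (washout or threshold growth would give LR-5)")

  category <- base
  if (!is.null(ancillary)) {
    mal <- any(vapply(ancillary$favoring_malignancy, tristate_yes, TRUE))
    ben <- any(vapply(ancillary$favoring_benignity, tristate_yes, TRUE))
    idx <- match(base, LR_LEVELS)
    if (mal && !ben) {
      # upgrade by one, capped at LR-4: no ancillary path to LR-5
      category <- if (idx >= 4L) base else LR_LEVELS[min(idx + 1L, 4L)]
      rationale <- c(rationale, sprintf(
        "ancillary upgrade (malignancy-favouring present, capped at LR-4): %s -> %s",
        base, category))
    } else if (ben && !mal) {
      category <- LR_LEVELS[max(idx - 1L, 1L)]
      rationale <- c(rationale, sprintf(
        "ancillary downgrade (benignity-favouring present): %s -> %s", base, category))
    } else if (ben && mal) {
      rationale <- c(rationale,
        "ancillary features favour both malignancy and benignity: no adjustment")
    }
  }

  structure(list(category = category, base_category = base,
                 rationale = rationale, n_features = n,
                 features_present = names(feats)[feats],
                 size_bin = bin, aphe = major$aphe),
            class = "lirads_result")
}

#' @export
print.lirads_result <- function(x, ...) {
  cat(sprintf("<lirads_result> %s (base %s)\n", x$category, x$base_category))
  for (r in x$rationale) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Classify a batch of measurement records
#'
#' Computes the arithmetic major features of every record (sizing in
#' `chosen_phase`), classifies each, and cross-tabulates the categories by
#' APHE status, size bin and additional-feature count. Per-record errors are
#' collected, not fatal.
#'
#' @param records data.frame of measurement records (see
#'   [measurement_record]).
#' @param chosen_phase best phase used for sizing every record (one of
#'   `native`, `art`, `pv`, `del`).
#' @param washout_tristate,growth_tristate optional character vectors
#'   overriding the arithmetic washout / threshold-growth results per record
#'   (e.g. visual readings).
#' @return list with `results` (per-record [classify_lirads] outputs or
#'   `NULL`), `errors` (messages keyed by lesion_id), and `histogram`, a
#'   data.frame keyed by (aphe, size_bin, n_features, category) with counts.
#' @export
batch_classify <- function(records, chosen_phase = "art",
                           washout_tristate = NULL, growth_tristate = NULL) {
  results <- vector("list", nrow(records))
  names(results) <- records$lesion_id
  errors <- character(0)
  key <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    res <- tryCatch({
      mf <- major_features(
        hu_lesion = c(native = r$hu_lesion_native, art = r$hu_lesion_art,
                      pv = r$hu_lesion_pv, del = r$hu_lesion_del),
        hu_liver = c(native = r$hu_liver_native, art = r$hu_liver_art,
                     pv = r$hu_liver_pv, del = r$hu_liver_del),
        diam_by_phase = c(native = r$diam_native, art = r$diam_art,
                          pv = r$diam_pv, del = r$diam_del),
        chosen_phase = c(native = "native", art = "arterial",
                         pv = "portal_venous", del = "delayed")[[chosen_phase]],
        capsule = r$capsule,
        prior_diam_mm = if (is.na(r$prior_diam_mm)) NULL else r$prior_diam_mm,
        prior_interval_days = if (is.na(r$prior_interval_days)) NULL else r$prior_interval_days
      )
      if (!is.null(washout_tristate)) mf$washout <- as_tristate(washout_tristate[i], "washout")
      if (!is.null(growth_tristate)) mf$threshold_growth <- as_tristate(growth_tristate[i], "threshold_growth")
      suppressWarnings(classify_lirads(mf))
    }, lirads_error = function(e) e)
    if (inherits(res, "lirads_error")) {
      errors[[as.character(r$lesion_id)]] <- conditionMessage(res)
      results[[i]] <- NULL
    } else {
      results[[i]] <- res
      k <- sprintf("%s|%s|%d|%s", res$aphe, res$size_bin, res$n_features, res$category)
      key[[k]] <- (if (is.null(key[[k]])) 0L else key[[k]]) + 1L
    }
  }
  hist_df <- if (length(key)) {
    parts <- do.call(rbind, strsplit(names(key), "|", fixed = TRUE))
    data.frame(aphe = parts[, 1], size_bin = parts[, 2],
               n_features = as.integer(parts[, 3]), category = parts[, 4],
               count = unlist(key, use.names = FALSE), stringsAsFactors = FALSE)
  } else data.frame(aphe = character(0), size_bin = character(0),
                    n_features = integer(0), category = character(0),
                    count = integer(0))
  list(results = results, errors = errors, histogram = hist_df)
}
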