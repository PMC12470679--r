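# Agreement statistics between visual and arithmetic assessments.

#' Paired-ratings contingency table
#'
#' A K x K table of counts `n_ij` with rows the first rater's category
#' (e.g. visual) and columns the second rater's (e.g. arithmetic).
#'
#' @param counts square matrix of non-negative integer counts.
#' @param labels optional category labels.
#' @return an object of class `paired_ratings`.
#' @export
paired_ratings <- function(counts, labels = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || nrow(counts) < 2)
    lirads_abort("counts must be a square matrix with K >= 2", "lirads_format_error")
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    lirads_abort("counts must be non-negative integers", "lirads_format_error")
  counts <- round(counts)
  if (is.null(labels)) labels <- rownames(counts)
  if (is.null(labels)) labels <- paste0("cat", seq_len(nrow(counts)))
  dimnames(counts) <- list(visual = labels, arithmetic = labels)
  structure(list(counts = counts, labels = labels), class = "paired_ratings")
}

#' @export
print.paired_ratings <- function(x, ...) {
  cat(sprintf("<paired_ratings> %dx%d, n = %d\n", nrow(x$counts), ncol(x$counts),
              sum(x$counts)))
  print(x$counts)
  invisible(x)
}

#' McNemar-Bowker test of symmetry
#'
#' Tests marginal homogeneity of two paired categorical ratings:
#' `chi2 = sum over i < j with n_ij + n_ji > 0 of (n_ij - n_ji)^2 /
#' (n_ij + n_ji)`, with one degree of freedom per included pair and an
#' upper-tail chi-square p-value. For K = 2 this is the classical McNemar
#' test without continuity correction. Diagonal counts never enter.
#'
#' @param t a [paired_ratings] table (or a square count matrix).
#' @return an `htest` object with `statistic`, `parameter` (df) and
#'   `p.value`. When every off-diagonal pair is empty, `p = 1` with `df = 0`
#'   and a warning.
#' @export
mcnemar_bowker <- function(t) {
  if (!inherits(t, "paired_ratings")) t <- paired_ratings(t)
  m <- t$counts
  chi2 <- 0; df <- 0L
  for (i in seq_len(nrow(m) - 1)) for (j in (i + 1):ncol(m)) {
    s <- m[i, j] + m[j, i]
    if (s > 0) {
      chi2 <- chi2 + (m[i, j] - m[j, i])^2 / s
      df <- df + 1L
    }
  }
  if (df == 0L) {
    lirads_warn("all off-diagonal pairs are empty: p = 1", "lirads_stats_warning")
    p <- 1
  } else p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  structure(list(
    statistic = c("McNemar-Bowker chi-squared" = chi2),
    parameter = c(df = df), p.value = p,
    method = "McNemar-Bowker test of symmetry (no continuity correction)",
    data.name = deparse(substitute(t))
  ), class = "htest")
}

#' Exact sign test
#'
#' Two-sided exact binomial test on the signs of paired differences
#' `a - b`; ties are dropped. `p = min(1, 2 * P(X >= max(#pos, #neg)))`
#' under Binomial(n, 1/2).
#'
#' @param a,b paired numeric vectors (e.g. sizes in two contrast phases).
#' @return an `htest` object. All-ties input gives `p = 1` with a warning.
#' @export
sign_test <- function(a, b) {
  if (length(a) != length(b) || !length(a))
    lirads_abort("a and b must be non-empty vectors of equal length", "lirads_format_error")
  d <- a - b
  d <- d[d != 0]
  if (!length(d)) {
    lirads_warn("all pairs are tied: p = 1", "lirads_stats_warning")
    return(structure(list(statistic = c("positive differences" = 0),
                          parameter = c(n = 0), p.value = 1,
                          method = "Exact sign test", data.name = "a - b"),
                     class = "htest"))
  }
  n <- length(d)
  pos <- sum(d > 0)
  k <- max(pos, n - pos)
  p <- min(1, 2 * sum(stats::dbinom(k:n, n, 0.5)))
  structure(list(statistic = c("positive differences" = pos),
                 parameter = c(n = n), p.value = p,
                 method = "Exact sign test (two-sided, ties dropped)",
                 data.name = "a - b"),
            class = "htest")
}

#' Percent agreement of a paired-ratings table
#'
#' `100 * trace / total`. The raw percentage is returned alongside its
#' half-up integer rounding used for reporting.
#'
#' @param t a [paired_ratings] table (or square count matrix).
#' @return list with `percent` (raw) and `percent_rounded` (half-up
#'   integer).
#' @export
percent_agreement <- function(t) {
  if (!inherits(t, "paired_ratings")) t <- paired_ratings(t)
  total <- sum(t$counts)
  if (total <= 0) lirads_abort("table is empty", "lirads_format_error")
  pct <- 100 * sum(diag(t$counts)) / total
  list(percent = pct, percent_rounded = round_half_up(pct))
}

#' Reconstruct counts from a percentage table
#'
#' Published agreement tables often give cells as percentages of the cohort
#' size; this inverts them: `counts = round(pct / 100 * n)` (half-up), with
#' a conservation check that the rounded counts sum back to `n` within K.
#'
#' @param percentages square matrix of cell percentages (>= 0).
#' @param n cohort size.
#' @param labels optional category labels.
#' @return a [paired_ratings] table.
#' @export
counts_from_percentages <- function(percentages, n, labels = NULL) {
  percentages <- as.matrix(percentages)
  if (any(percentages < 0))
    lirads_abort("percentages must be >= 0", "lirads_format_error")
  counts <- round_half_up(percentages / 100 * n)
  resid <- sum(counts) - n
  if (abs(resid) > nrow(counts))
    lirads_abort(sprintf(
      "rounded table does not conserve n: sum %d vs n %d (residual %+d)",
      sum(counts), n, resid), "lirads_stats_error")
  paired_ratings(counts, labels)
}
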