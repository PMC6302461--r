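#' Build the 2x2 contingency table behind one (factor, threshold) test
#'
#' Rows split the interactions at the read-count threshold `T` into
#' `A = {n >= T}` and its complement; columns split them into the factor's
#' positive set `B` and its complement:
#'
#' \preformatted{
#'           B (bound)   not B
#'   n >= T    a11        a21
#'   n <  T    a12        a22
#' }
#'
#' @param labels An `interaction_labels` object.
#' @param tf Factor name.
#' @param T Read-count threshold (>= 1).
#' @return A list of class `contingency_table` with cells `a11`, `a12`,
#'   `a21`, `a22` plus `tf` and `T`.
#' @export
contingency <- function(labels, tf, T) {
  stopifnot(inherits(labels, "interaction_labels"))
  if (T < 1) stopf("T must be >= 1")
  if (!tf %in% colnames(labels$labels)) stopf("unknown factor '%s'", tf)
  pos <- labels$labels[, tf]
  inA <- labels$n >= T
  structure(
    list(
      a11 = sum(inA & pos), a12 = sum(!inA & pos),
      a21 = sum(inA & !pos), a22 = sum(!inA & !pos),
      tf = tf, T = T
    ),
    class = "contingency_table"
  )
}

# Vectorized Pearson chi-square on 2x2 cells; returns NA where any margin is
# zero (untestable). Optional Yates continuity correction.
pearson_chisq <- function(a11, a12, a21, a22, yates = FALSE) {
  N <- a11 + a12 + a21 + a22
  r1 <- a11 + a21 # |A|
  r2 <- a12 + a22
  c1 <- a11 + a12 # |B|
  c2 <- a21 + a22
  testable <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
  d <- abs(a11 * a22 - a12 * a21)
  if (yates) d <- pmax(0, d - N / 2)
  stat <- ifelse(testable, N * d^2 / (r1 * r2 * c1 * c2), NA_real_)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       testable = testable)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Uncorrected Pearson statistic with 1 degree of freedom; the p-value is the
#' upper tail of the chi-square distribution. Tables with an empty margin are
#' reported untestable (`testable = FALSE`, `NA` statistic) rather than
#' raising a numeric error.
#'
#' @param table A `contingency_table` (or list with cells `a11`..`a22`).
#' @param yates Apply the Yates continuity correction (default off).
#' @return A list with `statistic`, `p`, and `testable`.
#' @export
chisq_test <- function(table, yates = FALSE) {
  r <- pearson_chisq(table$a11, table$a12, table$a21, table$a22, yates = yates)
  list(statistic = r$statistic, p = r$p, testable = r$testable)
}

#' Chi-square threshold scan over all factors
#'
#' Tests every (factor, threshold) pair on the inclusive integer grid
#' `T_min..T_max` (7..45 by default, 39 thresholds). Raw p-values are
#' Bonferroni-adjusted; the family is either all testable (factor, threshold)
#' cells (`"global"`, default) or each factor's testable thresholds
#' (`"per-tf"`). Cells with an empty margin are untestable and excluded from
#' the family size.
#'
#' @param labels An `interaction_labels` object.
#' @param T_min,T_max Inclusive threshold range (default 7..45).
#' @param alpha Significance level for the per-factor summary counts.
#' @param yates Continuity correction flag, passed to the cell tests.
#' @param family Bonferroni family: `"global"` or `"per-tf"`.
#' @return A `chisq_scan` object: `cells` (one row per factor x threshold
#'   with the four table cells, statistic, `p`, `p_adj`, `testable`),
#'   `summary` (per factor: thresholds with raw p < alpha and with adjusted
#'   p < alpha), and provenance (`family`, family size `m`, `alpha`).
#' @export
chisq_scan <- function(labels, T_min = 7, T_max = 45, alpha = 0.05,
                       yates = FALSE, family = c("global", "per-tf")) {
  stopifnot(inherits(labels, "interaction_labels"))
  family <- match.arg(family)
  if (T_min > T_max) stopf("T_min (%d) must be <= T_max (%d)", T_min, T_max)
  T_grid <- seq.int(T_min, T_max)
  tc <- threshold_counts(labels, T_grid)
  tfs <- colnames(labels$labels)
  nT <- length(T_grid)
  a11 <- as.vector(tc$size_AB)                       # n >= T and bound
  a21 <- rep(tc$size_A, times = length(tfs)) - a11   # n >= T, not bound
  a12 <- rep(tc$total_pos, each = nT) - a11          # n < T, bound
  a22 <- tc$total - a11 - a21 - a12
  ch <- pearson_chisq(a11, a12, a21, a22, yates = yates)
  cells <- data.frame(
    tf = rep(tfs, each = nT), T = rep(T_grid, times = length(tfs)),
    a11 = a11, a12 = a12, a21 = a21, a22 = a22,
    statistic = ch$statistic, p = ch$p, testable = ch$testable,
    stringsAsFactors = FALSE
  )
  if (family == "global") {
    m <- sum(cells$testable)
    cells$p_adj <- pmin(1, cells$p * m)
  } else {
    m_tf <- tapply(cells$testable, cells$tf, sum)[cells$tf]
    cells$p_adj <- pmin(1, cells$p * as.numeric(m_tf))
    m <- as.list(tapply(cells$testable, cells$tf, sum))
  }
  summ <- data.frame(
    tf = tfs,
    n_raw_sig = as.integer(tapply(
      cells$testable & !is.na(cells$p) & cells$p < alpha, cells$tf, sum
    )[tfs]),
    n_adj_sig = as.integer(tapply(
      cells$testable & !is.na(cells$p_adj) & cells$p_adj < alpha, cells$tf, sum
    )[tfs]),
    stringsAsFactors = FALSE
  )
  structure(
    list(
      cells = cells[, c("tf", "T", "a11", "a12", "a21", "a22",
                        "statistic", "p", "p_adj", "testable")],
      summary = summ,
      family = family, m = m, alpha = alpha, yates = yates,
      T_min = T_min, T_max = T_max
    ),
    class = "chisq_scan"
  )
}

#' @export
print.chisq_scan <- function(x, ...) {
  cat(sprintf(
    "<chisq_scan> %d factors x thresholds %d..%d; %d factor(s) with adjusted p < %.2g\n",
    length(unique(x$cells$tf)), x$T_min, x$T_max,
    sum(x$summary$n_adj_sig > 0), x$alpha
  ))
  invisible(x)
}

#' Factors significant in the chi-square scan
#'
#' A factor is called significant if at least one threshold reaches an
#' adjusted p below `alpha`. The list is ordered by the number of significant
#' thresholds (descending), ties broken alphabetically.
#'
#' @param result A `chisq_scan` object.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of factor names (possibly empty).
#' @export
significant_tfs <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "chisq_scan"))
  cells <- result$cells
  n_sig <- tapply(
    cells$testable & !is.na(cells$p_adj) & cells$p_adj < alpha,
    cells$tf, sum
  )
  hits <- n_sig[n_sig >= 1]
  if (length(hits) == 0L) return(character())
  names(hits)[order(-as.integer(hits), names(hits))]
}
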