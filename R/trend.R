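#' Cochran-Armitage-style test for trend in proportions
#'
#' Given successes `x_i` of `n_i` trials at ordered score `w_i`, tests
#' whether the proportion changes linearly with the score. With the pooled
#' proportion `pbar = sum(x) / sum(n)` the statistic is
#' \deqn{\frac{[\sum_i w_i (x_i - n_i \bar p)]^2}{\bar p (1-\bar p)
#'   [\sum_i n_i w_i^2 - (\sum_i n_i w_i)^2 / \sum_i n_i]}}
#' and is referred to the chi-square distribution with 1 degree of freedom.
#' The sign of the numerator's root, `sum(w_i (x_i - n_i pbar))`, is
#' returned as the trend direction (increasing vs decreasing), which the
#' chi-square statistic alone cannot distinguish.
#'
#' Degenerate inputs — pooled proportion 0 or 1, or a zero score variance —
#' are reported untestable rather than raising a numeric error.
#'
#' @param x Successes per level (here: `|A ∩ B|` per threshold).
#' @param n Totals per level (here: `|A|` per threshold).
#' @param w Strictly increasing numeric scores (here: the thresholds).
#' @return A list with `statistic`, `p`, `df = 1`, `direction` (+1/-1/0),
#'   and `testable`.
#' @export
prop_trend_test <- function(x, n, w = seq_along(x)) {
  if (length(x) < 2L) stopf("need at least 2 levels")
  if (length(n) != length(x) || length(w) != length(x)) {
    stopf("x, n, w must have equal length")
  }
  if (any(x < 0) || any(x > n)) stopf("need 0 <= x <= n at every level")
  if (is.unsorted(w, strictly = TRUE)) stopf("scores w must be strictly increasing")
  N <- sum(n)
  pbar <- sum(x) / N
  num_root <- sum(w * (x - n * pbar))
  denom <- pbar * (1 - pbar) * (sum(n * w^2) - sum(n * w)^2 / N)
  if (pbar <= 0 || pbar >= 1 || denom <= 0) {
    return(list(statistic = NA_real_, p = NA_real_, df = 1L,
                direction = 0, testable = FALSE))
  }
  stat <- num_root^2 / denom
  list(
    statistic = stat,
    p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
    df = 1L, direction = sign(num_root), testable = TRUE
  )
}

#' Trend-test scan over factors and read ranges
#'
#' Runs [prop_trend_test()] once per (factor, range): the levels are the
#' defined thresholds inside the range, with `x = |A ∩ B|`, `n = |A|` and the
#' threshold itself as the score. P-values are Bonferroni-adjusted over all
#' testable (factor, range) pairs.
#'
#' @param curves A `ratio_curves` object.
#' @param ranges List of inclusive threshold ranges (default
#'   [default_ranges()], the same five ranges as the elastic net).
#' @return A `trend_scan` object: `tests` (one row per factor x range with
#'   statistic, `p`, `p_adj`, `direction`, `testable`), `summary` (per
#'   factor: minimum adjusted p and its direction), family size `m`.
#' @export
run_trend_scan <- function(curves, ranges = default_ranges()) {
  stopifnot(inherits(curves, "ratio_curves"))
  tfs <- attr(curves, "tfs")
  rows <- list()
  for (r in seq_along(ranges)) {
    rng <- ranges[[r]]
    sub <- curves[curves$T >= rng[1L] & curves$T <= rng[2L] & curves$defined, ,
      drop = FALSE
    ]
    for (tf in tfs) {
      s <- sub[sub$tf == tf, , drop = FALSE]
      res <- if (nrow(s) < 2L) {
        list(statistic = NA_real_, p = NA_real_, direction = 0, testable = FALSE)
      } else {
        prop_trend_test(s$size_AB, s$size_A, s$T)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, range = sprintf("n%d_%d", rng[1L], rng[2L]),
        statistic = res$statistic, p = res$p,
        direction = res$direction, testable = res$testable,
        stringsAsFactors = FALSE
      )
    }
  }
  tests <- do.call(rbind, rows)
  m <- sum(tests$testable)
  tests$p_adj <- pmin(1, tests$p * m)
  summ <- do.call(rbind, lapply(split(tests, tests$tf), function(d) {
    ok <- d$testable
    if (!any(ok)) {
      return(data.frame(tf = d$tf[1L], min_p_adj = NA_real_, direction = 0,
                        testable = FALSE, stringsAsFactors = FALSE))
    }
    i <- which(ok)[which.min(d$p_adj[ok])]
    data.frame(tf = d$tf[1L], min_p_adj = d$p_adj[i], direction = d$direction[i],
               testable = TRUE, stringsAsFactors = FALSE)
  }))
  summ <- summ[match(tfs, summ$tf), , drop = FALSE]
  rownames(summ) <- NULL
  tests <- tests[, c("tf", "range", "statistic", "p", "p_adj", "direction", "testable")]
  structure(list(tests = tests, summary = summ, m = m), class = "trend_scan")
}

#' @export
print.trend_scan <- function(x, ...) {
  sig <- sum(x$summary$testable & !is.na(x$summary$min_p_adj) & x$summary$min_p_adj < 0.05)
  cat(sprintf(
    "<trend_scan> %d factors x %d ranges (family m = %d); %d factor(s) with min adjusted p < 0.05\n",
    nrow(x$summary), nrow(x$tests) / nrow(x$summary), x$m, sig
  ))
  invisible(x)
}
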