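#' Build the regression design for one read range
#'
#' The regression views each integer read level `n` in the range as one
#' observation: the response is `n` itself and the predictors are every
#' factor's overlapping ratio at threshold `n`. With ~100 factors and 35-55
#' levels the predictor count far exceeds the observation count, which is
#' the regime the elastic net targets. Levels at which any factor's ratio is
#' undefined (empty `A`) are dropped and recorded.
#'
#' @param curves A `ratio_curves` object covering the range.
#' @param range Length-2 integer vector `c(n_lo, n_hi)` (inclusive).
#' @return A list of class `design_matrix`: `x` (levels x factors ratio
#'   matrix), `y` (read levels), `range`, `dropped` (levels removed).
#' @export
build_design <- function(curves, range) {
  stopifnot(inherits(curves, "ratio_curves"), length(range) == 2L)
  levels <- seq.int(range[1L], range[2L])
  T_grid <- attr(curves, "T_grid")
  if (!all(levels %in% T_grid)) {
    stopf("ratio curves do not cover range [%d,%d]", range[1L], range[2L])
  }
  tfs <- attr(curves, "tfs")
  sub <- curves[curves$T %in% levels, , drop = FALSE]
  x <- matrix(NA_real_, length(levels), length(tfs), dimnames = list(levels, tfs))
  x[cbind(match(sub$T, levels), match(sub$tf, tfs))] <- sub$ratio
  usable <- rowSums(is.na(x)) == 0L
  dropped <- levels[!usable]
  if (length(dropped) > 0L) {
    message(sprintf(
      "build_design: dropped %d level(s) with undefined ratios (%s)",
      length(dropped), paste(dropped, collapse = ", ")
    ))
  }
  x <- x[usable, , drop = FALSE]
  if (nrow(x) < 10L) {
    stopf("range [%d,%d] leaves %d usable levels; need >= 10", range[1L], range[2L], nrow(x))
  }
  structure(
    list(x = x, y = as.numeric(levels[usable]), range = range, dropped = dropped),
    class = "design_matrix"
  )
}

#' One elastic-net fit with cross-validated penalty
#'
#' Fits `y ~ x` with the elastic-net penalty (mixing weight `mixing` between
#' the lasso and ridge extremes), choosing the penalty strength by k-fold
#' cross-validation minimizing mean squared error. Predictors are
#' standardized internally and coefficients are reported on the original
#' scale; the intercept is unpenalized. Selected factors are those with a
#' nonzero coefficient at the CV-optimal penalty. When the rows are too few
#' for the requested fold count (`rows < 2 * folds`) the fold count falls
#' back to `max(3, rows %/% 5)`.
#'
#' @param design A `design_matrix` (or list with `x`, `y`).
#' @param mixing Elastic-net mixing weight in (0, 1]; 1 = lasso. Default 0.5.
#' @param folds Cross-validation fold count (default 10).
#' @param seed Integer seed controlling fold assignment (and hence the fit).
#' @return A list with `selected` (factor names), `beta` (named coefficients
#'   of the selected factors), `lambda` (chosen penalty), `folds_used`.
#' @export
fit_once <- function(design, mixing = 0.5, folds = 10, seed = 1L) {
  x <- design$x
  y <- design$y
  if (nrow(x) < 3L) stopf("need at least 3 rows to fit")
  if (mixing <= 0 || mixing > 1) stopf("mixing must be in (0, 1]")
  if (stats::var(y) == 0 || all(apply(x, 2L, stats::var) == 0)) {
    warning("constant response or all-constant predictors; nothing selected")
    return(list(selected = character(), beta = numeric(), lambda = NA_real_,
                folds_used = NA_integer_))
  }
  folds_used <- if (nrow(x) < 2L * folds) max(3L, nrow(x) %/% 5L) else as.integer(folds)
  fit <- with_seed(seed, {
    foldid <- sample(rep_len(seq_len(folds_used), nrow(x)))
    glmnet::cv.glmnet(x, y, alpha = mixing, foldid = foldid, standardize = TRUE)
  })
  cf <- as.matrix(stats::coef(fit, s = "lambda.min"))[, 1L]
  cf <- cf[setdiff(names(cf), "(Intercept)")]
  sel <- cf[cf != 0]
  list(
    selected = names(sel), beta = sel, lambda = fit$lambda.min,
    folds_used = folds_used
  )
}

default_ranges <- function() list(c(6, 40), c(6, 45), c(6, 50), c(6, 55), c(6, 60))

#' Bootstrapped elastic-net selection of factors tracking read intensity
#'
#' For each of the read ranges (by default the five ranges 6..40 through
#' 6..60), the design rows are resampled with replacement `B` times and an
#' elastic-net model is fitted to each resample. A factor's stability score
#' is the number of resamples in which it kept a nonzero coefficient. A
#' factor is selected if its count exceeds `threshold * B` in any single
#' range, or `threshold * (B * n_ranges)` in total (with the defaults: more
#' than 25 of 500 per range or 125 of 2500 overall); both criteria are
#' recorded and their union is the selected set. Child seeds for every
#' resample derive deterministically from `seed`, so a full run is exactly
#' reproducible.
#'
#' @param curves A `ratio_curves` object.
#' @param ranges List of inclusive read ranges (default [default_ranges()]).
#' @param B Bootstrap resamples per range (default 500).
#' @param threshold Selection-frequency cutoff as a fraction (default 0.05).
#' @param mixing,folds Passed to [fit_once()].
#' @param seed Master seed.
#' @return A `bootstrap_selection` object: per-factor data.frame with one
#'   count column per range, `total`, `mean_beta` (mean coefficient over the
#'   resamples where selected), `sign_consistency` (share of those resamples
#'   agreeing with the majority sign), the two criterion flags, and
#'   `selected`; plus a `params` list.
#' @export
bootstrap_select <- function(curves, ranges = default_ranges(), B = 500,
                             threshold = 0.05, mixing = 0.5, folds = 10,
                             seed = 1L) {
  stopifnot(inherits(curves, "ratio_curves"))
  if (B < 1) stopf("B must be >= 1")
  tfs <- attr(curves, "tfs")
  nr <- length(ranges)
  seeds <- matrix(derive_seeds(seed, nr * B), nrow = nr)
  counts <- matrix(0L, length(tfs), nr,
    dimnames = list(tfs, vapply(ranges, function(r) sprintf("n%d_%d", r[1L], r[2L]), ""))
  )
  beta_sum <- beta_pos <- beta_neg <- stats::setNames(numeric(length(tfs)), tfs)
  for (r in seq_len(nr)) {
    design <- build_design(curves, ranges[[r]])
    nrows <- nrow(design$x)
    for (b in seq_len(B)) {
      sb <- seeds[r, b]
      idx <- with_seed(sb, sample.int(nrows, nrows, replace = TRUE))
      boot <- list(x = design$x[idx, , drop = FALSE], y = design$y[idx])
      fit <- suppressWarnings(
        fit_once(boot, mixing = mixing, folds = folds, seed = sb + 1L)
      )
      if (length(fit$selected) > 0L) {
        counts[fit$selected, r] <- counts[fit$selected, r] + 1L
        beta_sum[fit$selected] <- beta_sum[fit$selected] + fit$beta
        beta_pos[fit$selected] <- beta_pos[fit$selected] + (fit$beta > 0)
        beta_neg[fit$selected] <- beta_neg[fit$selected] + (fit$beta < 0)
      }
    }
  }
  total <- rowSums(counts)
  mean_beta <- ifelse(total > 0, beta_sum / total, NA_real_)
  sign_cons <- ifelse(total > 0, pmax(beta_pos, beta_neg) / total, NA_real_)
  sel_range <- apply(counts, 1L, function(cnt) any(cnt > threshold * B))
  sel_total <- total > threshold * (B * nr)
  df <- data.frame(
    tf = tfs, counts, total = as.integer(total),
    mean_beta = as.numeric(mean_beta),
    sign_consistency = as.numeric(sign_cons),
    selected_per_range = sel_range, selected_total = sel_total,
    selected = sel_range | sel_total,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(
    list(
      selection = df,
      params = list(
        B = B, threshold = threshold, mixing = mixing, folds = folds,
        seed = seed, ranges = ranges,
        per_range_cutoff = threshold * B,
        total_cutoff = threshold * B * nr
      )
    ),
    class = "bootstrap_selection"
  )
}

#' @export
print.bootstrap_selection <- function(x, ...) {
  cat(sprintf(
    "<bootstrap_selection> %d factors, B = %d x %d ranges; %d selected (> %g%% rule)\n",
    nrow(x$selection), x$params$B, length(x$params$ranges),
    sum(x$selection$selected), 100 * x$params$threshold
  ))
  invisible(x)
}

#' Factors selected by the bootstrap elastic net
#'
#' Ordered by total selection count (descending), ties broken alphabetically.
#'
#' @param bs A `bootstrap_selection` object.
#' @return Character vector of factor names.
#' @export
selected_tfs <- function(bs) {
  stopifnot(inherits(bs, "bootstrap_selection"))
  df <- bs$selection[bs$selection$selected, , drop = FALSE]
  df$tf[order(-df$total, df$tf)]
}
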