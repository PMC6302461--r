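#' Fill in and validate a pipeline configuration
#'
#' Every parameter defaults to the study's stated value: 1,000-bp bins, keep
#' interactions with at least 6 reads, drop intra-chromosomal pairs closer
#' than one bin, analyse the inter-chromosomal subset, chi-square thresholds
#' 7..45 at alpha 0.05 with global Bonferroni, elastic-net mixing 0.5 with
#' 10-fold cross-validation, 500 bootstrap resamples over the five read
#' ranges 6..40 through 6..60, and the 5% selection rule (per-range cutoff
#' 25, total cutoff 125). Cross-field contradictions are reported together
#' in one error.
#'
#' @param config A (possibly partial) named list of settings; `list()` or
#'   `NULL` yields the full default configuration.
#' @return The normalized configuration (class `run_config`), including the
#'   derived `per_range_cutoff` and `total_cutoff`.
#' @export
validate_config <- function(config = list()) {
  if (is.null(config)) config <- list()
  defaults <- list(
    bin_size = 1000,
    min_reads = 6,
    min_separation_bins = 2,
    subset = "inter",
    T_min = 7,
    T_max = 45,
    alpha = 0.05,
    bonferroni_family = "global",
    yates = FALSE,
    curve_T_min = 6,
    curve_T_max = 100,
    enet_mixing = 0.5,
    enet_folds = 10,
    enet_B = 500,
    enet_ranges = default_ranges(),
    enet_threshold = 0.05,
    trend_ranges = NULL, # NULL: reuse enet_ranges
    export_T = c(20, 40),
    seed = 1L
  )
  unknown <- setdiff(names(config), c(
    names(defaults),
    c("contacts", "tfbs", "chrom_sizes", "sim")
  ))
  if (length(unknown)) {
    stopf("unknown configuration field(s): %s", paste(unknown, collapse = ", "))
  }
  # shallow merge: user fields replace defaults wholesale (modifyList would
  # try to merge list-valued fields like enet_ranges element-wise)
  cfg <- defaults
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)
  if (cfg$bin_size < 1) note("bin_size must be >= 1")
  if (cfg$min_reads < 1) note("min_reads must be >= 1")
  if (cfg$min_separation_bins < 1) note("min_separation_bins must be >= 1")
  if (!cfg$subset %in% c("all", "inter", "intra")) {
    note("subset must be one of all/inter/intra")
  }
  if (cfg$T_min > cfg$T_max) note(sprintf("T range [%d,%d] is empty", cfg$T_min, cfg$T_max))
  if (cfg$alpha <= 0 || cfg$alpha > 1) note("alpha must be in (0, 1]")
  if (!cfg$bonferroni_family %in% c("global", "per-tf")) {
    note("bonferroni_family must be 'global' or 'per-tf'")
  }
  if (cfg$curve_T_min > cfg$curve_T_max) note("curve T grid is empty")
  if (cfg$enet_mixing <= 0 || cfg$enet_mixing > 1) note("enet_mixing must be in (0, 1]")
  if (cfg$enet_folds < 3) note("enet_folds must be >= 3")
  if (cfg$enet_B < 1) note("enet_B must be >= 1")
  if (cfg$enet_threshold < 0 || cfg$enet_threshold >= 1) {
    note("enet_threshold must be in [0, 1)")
  }
  for (r in cfg$enet_ranges) {
    if (length(r) != 2L || r[1L] > r[2L]) note("each enet range must be c(lo, hi) with lo <= hi")
    else {
      if (r[1L] < cfg$min_reads) note(sprintf(
        "enet range [%d,%d] starts below min_reads (%d)", r[1L], r[2L], cfg$min_reads
      ))
      if (r[1L] < cfg$curve_T_min || r[2L] > cfg$curve_T_max) note(sprintf(
        "enet range [%d,%d] outside the curve grid [%d,%d]",
        r[1L], r[2L], cfg$curve_T_min, cfg$curve_T_max
      ))
    }
  }
  if (length(problems)) {
    stopf("invalid configuration:\n  - %s", paste(problems, collapse = "\n  - "))
  }
  cfg$trend_ranges <- cfg$trend_ranges %||% cfg$enet_ranges
  cfg$per_range_cutoff <- cfg$enet_threshold * cfg$enet_B
  cfg$total_cutoff <- cfg$enet_threshold * cfg$enet_B * length(cfg$enet_ranges)
  structure(cfg, class = "run_config")
}

#' Run the full enrichment pipeline
#'
#' Executes bin -> filter -> subset -> label -> ratio curves -> chi-square
#' scan -> bootstrap elastic net -> trend scan -> combine -> link export on
#' either a simulated study or on-disk inputs, logging record counts at each
#' filtering step. When `out_dir` is given every stage's table is written as
#' TSV together with a provenance JSON holding the fully-resolved
#' configuration, so a result bundle is regeneratable; reruns with the same
#' configuration and seed are byte-identical.
#'
#' @param config Passed through [validate_config()]. Supply either `sim` (a
#'   [sim_config()]; the default when no input paths are given) or the three
#'   paths `contacts`, `tfbs`, `chrom_sizes`.
#' @param out_dir Optional output directory for the result bundle.
#' @param quiet Suppress progress messages.
#' @return A list of class `pipeline_result` with every stage's object:
#'   `layout`, `iset_raw`, `iset`, `map`, `labels`, `distribution`,
#'   `curves`, `scan`, `chisq_tfs`, `enet`, `enet_tfs`, `trend`, `combined`,
#'   `links` (one BEDPE table per `export_T`), `truth` (simulation only),
#'   and `config`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, quiet = FALSE) {
  cfg <- validate_config(config[setdiff(names(config), c("sim", "contacts", "tfbs", "chrom_sizes"))])
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))

  from_files <- !is.null(config$contacts)
  truth <- NULL
  if (from_files) {
    if (is.null(config$tfbs) || is.null(config$chrom_sizes)) {
      stopf("file input needs 'contacts', 'tfbs' and 'chrom_sizes'")
    }
    layout <- load_chrom_sizes(config$chrom_sizes)
    records <- read_contacts(config$contacts, layout)
    say("read %d contact records on %d chromosomes", nrow(records), length(layout$chrom))
    iset_raw <- bin_contacts(records, layout, cfg$bin_size)
    tf_records <- read_tfbs(config$tfbs, layout)
    tf_universe <- NULL
  } else {
    sim <- config$sim %||% sim_config(seed = cfg$seed)
    stopifnot(inherits(sim, "sim_config"))
    layout <- simulate_genome(sim)
    iset_raw <- simulate_interactions(layout, sim)
    say(
      "simulated %d interactions (%d inter-chromosomal)",
      nrow(iset_raw$interactions), sum(iset_raw$interactions$is_inter)
    )
  }
  say("binned: %d unique bin pairs, %.0f reads", nrow(iset_raw$interactions), sum(iset_raw$interactions$n))

  iset <- filter_interactions(iset_raw,
    min_reads = cfg$min_reads,
    min_separation_bins = cfg$min_separation_bins
  )
  say(
    "filtered: removed %d close intra pairs and %d low-read pairs; %d remain",
    iset$provenance$removed_distance, iset$provenance$removed_low_reads,
    nrow(iset$interactions)
  )
  iset <- subset_interactions(iset, cfg$subset)
  say("subset '%s': %d interactions", cfg$subset, nrow(iset$interactions))

  if (!from_files) {
    tfsim <- simulate_tfbs(layout, iset, sim)
    tf_records <- tfsim$records
    truth <- tfsim$truth
    tf_universe <- tfsim$truth$tf
  }
  map <- mark_bins(tf_records, layout, cfg$bin_size, tfs = tf_universe)
  labels <- label_interactions(iset, map)
  say("labelled %d interactions x %d factors", nrow(labels$labels), ncol(labels$labels))

  distribution <- count_distribution(iset)
  curves <- ratio_curves(labels, seq.int(cfg$curve_T_min, cfg$curve_T_max))

  scan <- chisq_scan(labels,
    T_min = cfg$T_min, T_max = cfg$T_max, alpha = cfg$alpha,
    yates = cfg$yates, family = cfg$bonferroni_family
  )
  chisq_tfs <- significant_tfs(scan, cfg$alpha)
  say("chi-square scan: %d significant factor(s)", length(chisq_tfs))

  empty_input <- nrow(labels$labels) == 0L
  if (empty_input) {
    warning("no interactions after filtering/subsetting; regression and trend stages skipped")
    enet <- NULL
    enet_tfs <- character()
    trend <- NULL
  } else {
    enet <- bootstrap_select(curves,
      ranges = cfg$enet_ranges, B = cfg$enet_B,
      threshold = cfg$enet_threshold, mixing = cfg$enet_mixing,
      folds = cfg$enet_folds, seed = cfg$seed
    )
    enet_tfs <- selected_tfs(enet)
    say("elastic net: %d selected factor(s)", length(enet_tfs))
    trend <- run_trend_scan(curves, cfg$trend_ranges)
  }
  combined <- combine_methods(chisq_tfs, enet %||% character())
  say("combined: %d factor(s) significant in both methods", length(combined$intersection))

  links <- lapply(cfg$export_T, function(Tt) {
    export_links(labels, combined$intersection, Tt)
  })
  names(links) <- sprintf("T%d", cfg$export_T)

  result <- structure(
    list(
      layout = layout, iset_raw = iset_raw, iset = iset, map = map,
      labels = labels, distribution = distribution, curves = curves,
      scan = scan, chisq_tfs = chisq_tfs, enet = enet, enet_tfs = enet_tfs,
      trend = trend, combined = combined, links = links, truth = truth,
      config = cfg
    ),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_bundle(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d interactions, %d factors; chi-square %d, elastic net %d, both %d\n",
    nrow(x$iset$interactions), ncol(x$labels$labels),
    length(x$chisq_tfs), length(x$enet_tfs), length(x$combined$intersection)
  ))
  invisible(x)
}

# Serialize every stage of a pipeline result as TSV + provenance JSON.
write_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  write_interactions(result$iset, file.path(out_dir, "interactions.tsv"))
  tsv(result$distribution, "count_distribution.tsv")
  tsv(as.data.frame(result$curves), "ratio_curves.tsv")
  tsv(result$scan$cells, "chisq_scan.tsv")
  tsv(result$scan$summary, "chisq_summary.tsv")
  if (!is.null(result$enet)) tsv(result$enet$selection, "enet_selection.tsv")
  if (!is.null(result$trend)) {
    tsv(result$trend$tests, "trend_tests.tsv")
    tsv(result$trend$summary, "trend_summary.tsv")
  }
  tsv(result$combined$evidence, "combined_evidence.tsv")
  writeLines(result$combined$intersection, file.path(out_dir, "combined_tfs.txt"))
  if (!is.null(result$truth)) tsv(result$truth, "truth.tsv")
  for (nm in names(result$links)) {
    Tt <- as.integer(sub("^T", "", nm))
    export_links(result$labels, result$combined$intersection, Tt,
      path = file.path(out_dir, sprintf("links_%s.bedpe", nm))
    )
  }
  prov <- unclass(result$config)
  prov$chisq_family_size <- result$scan$m
  if (!is.null(result$enet)) prov$enet_params <- result$enet$params[
    setdiff(names(result$enet$params), "ranges")
  ]
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(out_dir)
}

#' Plot overlapping-ratio curves
#'
#' Grey dashed lines for background factors, coloured solid lines for
#' `highlight` (e.g. the combined candidate set).
#'
#' @param curves A `ratio_curves` object.
#' @param highlight Factors to emphasize.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_ratio_curves <- function(curves, highlight = character(), ...) {
  stopifnot(inherits(curves, "ratio_curves"))
  tfs <- attr(curves, "tfs")
  T_grid <- attr(curves, "T_grid")
  mat <- matrix(NA_real_, length(T_grid), length(tfs), dimnames = list(T_grid, tfs))
  mat[cbind(match(curves$T, T_grid), match(curves$tf, tfs))] <- curves$ratio
  bg <- setdiff(tfs, highlight)
  graphics::matplot(T_grid, mat[, bg, drop = FALSE],
    type = "l", lty = 2, col = "grey70",
    xlab = "read-count threshold T", ylab = "overlapping ratio |A∩B|/|A|", ...
  )
  if (length(highlight)) {
    cols <- grDevices::hcl.colors(max(3L, length(highlight)), "Dark 3")
    graphics::matlines(T_grid, mat[, highlight, drop = FALSE],
      lty = 1, lwd = 2, col = cols[seq_along(highlight)]
    )
    graphics::legend("topleft", legend = highlight, col = cols[seq_along(highlight)],
      lwd = 2, cex = 0.7, bty = "n"
    )
  }
  invisible(mat)
}
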