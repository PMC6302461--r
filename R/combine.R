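#' Intersect the chi-square and elastic-net candidate sets
#'
#' Factors called by both methods are the high-confidence candidates. The
#' intersection is ordered by elastic-net total selection count (descending)
#' when a `bootstrap_selection` is supplied, ties (or plain character input)
#' broken alphabetically. Commutative and idempotent in the two input sets.
#'
#' @param scan_sig Chi-square-significant factors: a character vector (e.g.
#'   from [significant_tfs()]).
#' @param enet_sel Elastic-net-selected factors: a character vector or a
#'   `bootstrap_selection` object (from which the selected set and ordering
#'   counts are taken).
#' @return A `combined_result` object: the two input sets, their
#'   `intersection`, and an `evidence` data.frame with one row per factor in
#'   the union and a flag per method.
#' @export
combine_methods <- function(scan_sig, enet_sel) {
  counts <- NULL
  if (inherits(enet_sel, "bootstrap_selection")) {
    counts <- stats::setNames(enet_sel$selection$total, enet_sel$selection$tf)
    enet_sel <- selected_tfs(enet_sel)
  }
  scan_sig <- unique(as.character(scan_sig))
  enet_sel <- unique(as.character(enet_sel))
  inter <- intersect(scan_sig, enet_sel)
  key <- if (is.null(counts)) {
    stats::setNames(numeric(length(inter)), inter)
  } else {
    ifelse(inter %in% names(counts), counts[inter], 0)
  }
  inter <- inter[order(-as.numeric(key), inter)]
  universe <- sort(union(scan_sig, enet_sel))
  evidence <- data.frame(
    tf = universe,
    chisq = universe %in% scan_sig,
    elastic_net = universe %in% enet_sel,
    both = universe %in% inter,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      chisq_tfs = scan_sig, enet_tfs = enet_sel,
      intersection = inter, evidence = evidence
    ),
    class = "combined_result"
  )
}

#' @export
print.combined_result <- function(x, ...) {
  cat(sprintf(
    "<combined_result> chi-square: %d, elastic net: %d, both: %d\n",
    length(x$chisq_tfs), length(x$enet_tfs), length(x$intersection)
  ))
  if (length(x$intersection)) {
    cat("  intersection:", paste(x$intersection, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export high-intensity interactions of selected factors as BEDPE links
#'
#' One row per interaction with at least `T` reads that is positive for any
#' of the listed factors; the name column holds the comma-joined names of
#' the matching factors. Coordinates are 0-based half-open bin intervals.
#' The output is a standard 10-column BEDPE suitable as circos link input.
#'
#' @param labels An `interaction_labels` object.
#' @param tfs Factors whose interactions to export.
#' @param T Minimum read count.
#' @param path Optional output path; when given, rows are written below a
#'   `#` header line.
#' @return (Invisibly) the BEDPE data.frame.
#' @export
export_links <- function(labels, tfs, T, path = NULL) {
  stopifnot(inherits(labels, "interaction_labels"))
  if (T < 1) stopf("T must be >= 1")
  missing <- setdiff(tfs, colnames(labels$labels))
  if (length(missing)) stopf("unknown factor '%s'", missing[1L])
  iset <- labels$interactions
  bins <- make_bins(iset$layout, iset$bin_size)
  x <- iset$interactions
  sub <- labels$labels[, tfs, drop = FALSE]
  keep <- labels$n >= T & rowSums(sub) > 0
  x <- x[keep, , drop = FALSE]
  sub <- sub[keep, , drop = FALSE]
  name <- apply(sub, 1L, function(row) paste(tfs[row], collapse = ","))
  out <- data.frame(
    chrom1 = bins$chrom[x$bin_a + 1L],
    start1 = bins$start[x$bin_a + 1L], end1 = bins$end[x$bin_a + 1L],
    chrom2 = bins$chrom[x$bin_b + 1L],
    start2 = bins$start[x$bin_b + 1L], end2 = bins$end[x$bin_b + 1L],
    name = if (nrow(x)) name else character(),
    score = x$n, strand1 = rep(".", nrow(x)), strand2 = rep(".", nrow(x)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (!is.null(path)) {
    header <- paste(
      "#chrom1", "start1", "end1", "chrom2", "start2", "end2",
      "name", "score", "strand1", "strand2",
      sep = "\t"
    )
    writeLines(header, path)
    if (nrow(out)) {
      utils::write.table(out, path,
        sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE, append = TRUE
      )
    }
  }
  invisible(out)
}
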