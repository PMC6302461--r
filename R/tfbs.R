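#' Read transcription-factor binding sites from a BED4+ file
#'
#' The 4th BED column carries the factor name; one file may interleave many
#' factors. Intervals are validated against the layout (0-based, half-open,
#' within chromosome bounds).
#'
#' @param path Path to the BED file.
#' @param layout A [genome_layout()].
#' @return A data.frame of binding-site records with columns `tf`, `chrom`,
#'   `start`, `end`.
#' @export
read_tfbs <- function(path, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  gr <- tryCatch(
    rtracklayer::import(path, format = "bed"),
    error = function(e) stopf("failed to parse BED file '%s': %s", path, conditionMessage(e))
  )
  if (length(gr) == 0L) stopf("BED file '%s' contains no records", path)
  nm <- gr$name
  if (is.null(nm) || anyNA(nm) || any(!nzchar(nm))) {
    stopf("BED file '%s': every record needs a factor name in column 4", path)
  }
  rec <- data.frame(
    tf = as.character(nm),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L, # GRanges is 1-based closed
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  validate_tfbs(rec, layout)
  rec
}

validate_tfbs <- function(rec, layout) {
  ci <- match(rec$chrom, layout$chrom)
  if (anyNA(ci)) stopf("TFBS record on unknown chromosome '%s'", rec$chrom[is.na(ci)][1L])
  if (any(rec$start >= rec$end)) {
    b <- which(rec$start >= rec$end)[1L]
    stopf("TFBS record %d: start (%d) must be < end (%d)", b, rec$start[b], rec$end[b])
  }
  bad <- rec$start < 0 | rec$end > layout$length[ci]
  if (any(bad)) {
    b <- which(bad)[1L]
    stopf(
      "TFBS record %d: interval [%d,%d) outside chromosome '%s'",
      b, rec$start[b], rec$end[b], rec$chrom[b]
    )
  }
  invisible(rec)
}

#' Map binding sites to genome bins
#'
#' A bin is bound by a factor iff any of the factor's sites overlaps the bin
#' by at least one bp; a site spanning a bin boundary marks every bin it
#' touches. Factors listed in `tfs` but absent from `records` are retained
#' with an empty bin set (they surface downstream as untestable rather than
#' silently disappearing).
#'
#' @param records Binding-site records from [read_tfbs()].
#' @param layout A [genome_layout()].
#' @param bin_size Bin width in bp.
#' @param tfs Optional character vector extending the factor universe beyond
#'   the names present in `records`.
#' @return A `tf_binding_map`: named list mapping each factor to its sorted
#'   set of bound 0-based global bin indices.
#' @export
mark_bins <- function(records, layout, bin_size = 1000, tfs = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  validate_tfbs(records, layout)
  universe <- sort(unique(c(as.character(records$tf), tfs)))
  off <- bin_offsets(layout, bin_size)
  ci <- match(records$chrom, layout$chrom)
  first_bin <- records$start %/% bin_size
  last_bin <- (records$end - 1L) %/% bin_size
  span <- last_bin - first_bin + 1L
  bin_idx <- as.integer(
    off$offset[rep(ci, span)] +
      unlist(lapply(seq_len(nrow(records)), function(i) first_bin[i]:last_bin[i]))
  )
  tf_of <- rep(records$tf, span)
  map <- lapply(universe, function(tf) sort(unique(bin_idx[tf_of == tf])))
  names(map) <- universe
  structure(map,
    class = "tf_binding_map",
    bin_size = bin_size, n_bins = off$total
  )
}

#' @export
print.tf_binding_map <- function(x, ...) {
  cat(sprintf(
    "<tf_binding_map> %d factors, %d-%d bound bins each (of %d bins)\n",
    length(x), min(lengths(x)), max(lengths(x)), attr(x, "n_bins")
  ))
  invisible(x)
}

#' Label interactions positive/negative per factor
#'
#' An interaction is positive for a factor iff at least one of its two bins
#' is bound by that factor (OR semantics; both-bound counts once).
#'
#' @param iset An `interaction_set`.
#' @param map A `tf_binding_map` built on the same layout and bin size.
#' @return An `interaction_labels` object: a logical matrix (interactions x
#'   factors) plus the aligned read-count vector and the interaction set.
#' @export
label_interactions <- function(iset, map) {
  stopifnot(inherits(iset, "interaction_set"), inherits(map, "tf_binding_map"))
  off <- bin_offsets(iset$layout, iset$bin_size)
  if (!identical(attr(map, "bin_size"), iset$bin_size) ||
    !identical(attr(map, "n_bins"), off$total)) {
    stopf("binding map and interaction set were built on different layouts/bin sizes")
  }
  x <- iset$interactions
  if (nrow(x) == 0L) {
    labels <- matrix(logical(), 0L, length(map), dimnames = list(NULL, names(map)))
  } else {
    labels <- vapply(map, function(bins) {
      (x$bin_a %in% bins) | (x$bin_b %in% bins)
    }, logical(nrow(x)))
    if (is.null(dim(labels))) {
      labels <- matrix(labels, nrow = nrow(x), dimnames = list(NULL, names(map)))
    }
  }
  structure(
    list(labels = labels, n = x$n, interactions = iset),
    class = "interaction_labels"
  )
}

#' @export
print.interaction_labels <- function(x, ...) {
  cat(sprintf(
    "<interaction_labels> %d interactions x %d factors (%.1f%% positive)\n",
    nrow(x$labels), ncol(x$labels), 100 * mean(x$labels)
  ))
  invisible(x)
}

# Shared machinery for threshold scans: for each threshold T in `T_grid`
# return |A| = #{n >= T} and per-factor |A ∩ B| via a single pass over the
# interactions sorted by decreasing read count.
threshold_counts <- function(labels, T_grid) {
  n <- labels$n
  M <- labels$labels
  ord <- order(n, decreasing = TRUE)
  n_sorted <- n[ord]
  if (nrow(M) > 0L) {
    cum_pos <- apply(M[ord, , drop = FALSE], 2L, cumsum)
    if (!is.matrix(cum_pos)) { # single interaction: apply() simplifies
      cum_pos <- matrix(cum_pos, nrow = nrow(M), dimnames = list(NULL, colnames(M)))
    }
  } else {
    cum_pos <- matrix(0, 0L, ncol(M), dimnames = list(NULL, colnames(M)))
  }
  # size of A at threshold T: number of sorted counts >= T
  size_A <- vapply(T_grid, function(Tt) sum(n_sorted >= Tt), numeric(1))
  size_AB <- matrix(0, length(T_grid), ncol(M), dimnames = list(NULL, colnames(M)))
  nonzero <- size_A > 0
  if (any(nonzero) && nrow(M) > 0L) {
    size_AB[nonzero, ] <- cum_pos[size_A[nonzero], , drop = FALSE]
  }
  list(size_A = size_A, size_AB = size_AB, total = length(n),
       total_pos = if (nrow(M) > 0L) colSums(M) else numeric(ncol(M)))
}

#' Overlapping-ratio curves across read-count thresholds
#'
#' For factor `tf` and threshold `T`, with `A` the interactions supported by
#' at least `T` reads and `B` the interactions positive for `tf`, the
#' overlapping ratio is `|A ∩ B| / |A|` — the fraction of at-least-T-intensity
#' interactions touching the factor's binding sites. Points where `A` is
#' empty are flagged undefined (`ratio = NA`), never emitted as 0.
#'
#' @param labels An `interaction_labels` object.
#' @param T_grid Ascending integer vector of thresholds (default `6:100`,
#'   the reporting grid; the chi-square scan uses 7..45).
#' @return A data.frame of class `ratio_curves` with columns `tf`, `T`,
#'   `size_A`, `size_AB`, `ratio`, `defined`.
#' @export
ratio_curves <- function(labels, T_grid = 6:100) {
  stopifnot(inherits(labels, "interaction_labels"))
  if (is.unsorted(T_grid, strictly = TRUE)) stopf("T_grid must be strictly ascending")
  tc <- threshold_counts(labels, T_grid)
  tfs <- colnames(labels$labels)
  out <- data.frame(
    tf = rep(tfs, each = length(T_grid)),
    T = rep(T_grid, times = length(tfs)),
    size_A = rep(tc$size_A, times = length(tfs)),
    size_AB = as.vector(tc$size_AB),
    stringsAsFactors = FALSE
  )
  out$defined <- out$size_A > 0
  out$ratio <- ifelse(out$defined, out$size_AB / out$size_A, NA_real_)
  structure(out, class = c("ratio_curves", "data.frame"), T_grid = T_grid, tfs = tfs)
}
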