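#' Read a Hi-C contact list
#'
#' Parses the five-column tab-separated contact dialect
#' `chrom1 pos1 chrom2 pos2 count`. Positions in the file are 1-based (the
#' common convention for Hi-C pair lists) and are converted to 0-based on
#' read; lines starting with `#` are ignored. Every record is validated
#' against the layout and errors name the offending file line.
#'
#' @param path Path to the contact file.
#' @param layout A [genome_layout()].
#' @return A data.frame of contact records with columns `chrom1`, `pos1`,
#'   `chrom2`, `pos2` (0-based), `count`, and `line` (source line number).
#' @export
read_contacts <- function(path, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(
      chrom1 = character(), pos1 = numeric(), chrom2 = character(),
      pos2 = numeric(), count = numeric(), line = integer(),
      stringsAsFactors = FALSE
    ))
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 5L)) {
    stopf("contact file line %d: expected 5 tab-separated fields", idx[nfield < 5L][1L])
  }
  field <- function(k) vapply(parts, `[[`, "", k)
  chrom1 <- field(1L)
  chrom2 <- field(3L)
  pos1 <- suppressWarnings(as.numeric(field(2L)))
  pos2 <- suppressWarnings(as.numeric(field(4L)))
  count <- suppressWarnings(as.numeric(field(5L)))
  for (nm in c("pos1", "pos2", "count")) {
    v <- get(nm)
    if (anyNA(v) || any(v != floor(v))) {
      stopf("contact file line %d: non-integer %s", idx[is.na(v) | v != floor(v)][1L], nm)
    }
  }
  if (any(count < 1)) {
    stopf("contact file line %d: count must be >= 1", idx[count < 1][1L])
  }
  ci1 <- match(chrom1, layout$chrom)
  ci2 <- match(chrom2, layout$chrom)
  if (anyNA(ci1) || anyNA(ci2)) {
    bad <- which(is.na(ci1) | is.na(ci2))[1L]
    nm <- if (is.na(ci1[bad])) chrom1[bad] else chrom2[bad]
    stopf("contact file line %d: unknown chromosome '%s'", idx[bad], nm)
  }
  # 1-based file positions -> 0-based internal coordinates
  pos1 <- pos1 - 1
  pos2 <- pos2 - 1
  bad <- pos1 < 0 | pos1 >= layout$length[ci1] | pos2 < 0 | pos2 >= layout$length[ci2]
  if (any(bad)) {
    stopf("contact file line %d: position out of chromosome bounds", idx[bad][1L])
  }
  data.frame(
    chrom1 = chrom1, pos1 = pos1, chrom2 = chrom2, pos2 = pos2,
    count = count, line = idx, stringsAsFactors = FALSE
  )
}

new_interaction_set <- function(interactions, layout, bin_size, provenance) {
  rownames(interactions) <- NULL
  structure(
    list(
      interactions = interactions, layout = layout, bin_size = bin_size,
      provenance = provenance
    ),
    class = "interaction_set"
  )
}

#' @export
print.interaction_set <- function(x, ...) {
  n <- nrow(x$interactions)
  cat(sprintf(
    "<interaction_set> %d bin pairs (%d inter-chromosomal), %.0f total reads, bin size %d bp\n",
    n, sum(x$interactions$is_inter), sum(x$interactions$n), x$bin_size
  ))
  invisible(x)
}

#' Aggregate contact records into bin-pair interactions
#'
#' Each contact end is assigned to its 1-kb (or `bin_size`) bin; the pair is
#' stored canonically (smaller global index first) and read counts of
#' identical pairs are summed. Records whose two ends fall in the same bin
#' cannot represent an interaction between two segments and are dropped; the
#' number of dropped records and reads is recorded in the provenance.
#'
#' @param records Contact records from [read_contacts()].
#' @param layout A [genome_layout()].
#' @param bin_size Bin width in bp.
#' @return An `interaction_set`: the interaction table (`bin_a`, `bin_b`,
#'   `n`, `is_inter`) plus layout, bin size, and provenance counts.
#' @export
bin_contacts <- function(records, layout, bin_size = 1000) {
  stopifnot(inherits(layout, "genome_layout"))
  if (nrow(records) == 0L) {
    empty <- data.frame(
      bin_a = integer(), bin_b = integer(), n = numeric(), is_inter = logical()
    )
    return(new_interaction_set(empty, layout, bin_size, list(
      records_in = 0L, same_bin_records_dropped = 0L, same_bin_reads_dropped = 0
    )))
  }
  b1 <- locate_bin(layout, records$chrom1, records$pos1, bin_size)
  b2 <- locate_bin(layout, records$chrom2, records$pos2, bin_size)
  same <- b1 == b2
  n_same <- sum(same)
  reads_same <- sum(records$count[same])
  if (n_same > 0L) {
    message(sprintf(
      "bin_contacts: dropped %d same-bin record(s) carrying %.0f reads", n_same, reads_same
    ))
  }
  b1 <- b1[!same]; b2 <- b2[!same]; cnt <- records$count[!same]
  bin_a <- pmin(b1, b2)
  bin_b <- pmax(b1, b2)
  key <- paste(bin_a, bin_b)
  agg <- rowsum(cnt, key, reorder = FALSE)
  first <- !duplicated(key)
  ord_a <- bin_a[first]; ord_b <- bin_b[first]
  n_agg <- as.numeric(agg[match(paste(ord_a, ord_b), rownames(agg)), 1L])
  # order canonically by (bin_a, bin_b) for deterministic output
  o <- order(ord_a, ord_b)
  bins <- make_bins(layout, bin_size)
  chrom_of <- bins$chrom[ord_a[o] + 1L]
  chrom_of_b <- bins$chrom[ord_b[o] + 1L]
  inter <- data.frame(
    bin_a = ord_a[o], bin_b = ord_b[o], n = n_agg[o],
    is_inter = chrom_of != chrom_of_b
  )
  new_interaction_set(inter, layout, bin_size, list(
    records_in = nrow(records),
    same_bin_records_dropped = n_same,
    same_bin_reads_dropped = reads_same
  ))
}

#' Apply the read-count and genomic-separation filters
#'
#' Two rules: (i) intra-chromosomal pairs of identical or adjacent bins
#' (genomic separation under one bin width) are unlikely to represent a real
#' interaction and are discarded; (ii) interactions supported by fewer than
#' `min_reads` reads (default: keep n >= 6, i.e. discard n <= 5) are treated
#' as noise and discarded. Counts removed by each rule are appended to the
#' set's provenance. The operation is idempotent.
#'
#' @param iset An `interaction_set`.
#' @param min_reads Minimum read count to keep (default 6).
#' @param min_separation_bins Minimum intra-chromosomal bin-index gap to keep
#'   (default 2, i.e. drop adjacent bins).
#' @return The filtered `interaction_set`.
#' @export
filter_interactions <- function(iset, min_reads = 6, min_separation_bins = 2) {
  stopifnot(inherits(iset, "interaction_set"))
  if (min_reads < 1) stopf("min_reads must be >= 1")
  if (min_separation_bins < 1) stopf("min_separation_bins must be >= 1")
  x <- iset$interactions
  # within a chromosome global indices are contiguous, so the global gap is
  # the within-chromosome gap for intra pairs
  too_close <- !x$is_inter & (x$bin_b - x$bin_a) < min_separation_bins
  x2 <- x[!too_close, , drop = FALSE]
  low <- x2$n < min_reads
  out <- x2[!low, , drop = FALSE]
  rownames(out) <- NULL
  prov <- iset$provenance
  prov$removed_distance <- sum(too_close) + (prov$removed_distance %||% 0L)
  prov$removed_low_reads <- sum(low) + (prov$removed_low_reads %||% 0L)
  prov$min_reads <- min_reads
  prov$min_separation_bins <- min_separation_bins
  new_interaction_set(out, iset$layout, iset$bin_size, prov)
}

#' Subset interactions by chromosomal relationship
#'
#' @param iset An `interaction_set`.
#' @param which One of `"all"`, `"inter"`, `"intra"`. The pipeline default is
#'   `"inter"`: the methods target inter-chromosomal interactions.
#' @return The subset `interaction_set` (possibly empty).
#' @export
subset_interactions <- function(iset, which = c("all", "inter", "intra")) {
  stopifnot(inherits(iset, "interaction_set"))
  which <- match.arg(which)
  x <- iset$interactions
  keep <- switch(which,
    all = rep(TRUE, nrow(x)),
    inter = x$is_inter,
    intra = !x$is_inter
  )
  prov <- iset$provenance
  prov$subset <- which
  new_interaction_set(x[keep, , drop = FALSE], iset$layout, iset$bin_size, prov)
}

#' Histogram of interaction read counts
#'
#' @param iset An `interaction_set`.
#' @return A data.frame with one row per observed read count `n`: the number
#'   of interactions with that count and the cumulative share of interactions
#'   with counts `<= n`.
#' @export
count_distribution <- function(iset) {
  stopifnot(inherits(iset, "interaction_set"))
  n <- iset$interactions$n
  if (length(n) == 0L) {
    return(data.frame(n = numeric(), count = integer(), cum_share = numeric()))
  }
  tab <- table(n)
  cnt <- as.integer(tab)
  data.frame(
    n = as.numeric(names(tab)),
    count = cnt,
    cum_share = cumsum(cnt) / sum(cnt)
  )
}

#' Write an interaction table as TSV
#'
#' Columns: `chrom_a`, `start_a`, `chrom_b`, `start_b`, `n`, `is_inter`
#' (0-based bin starts).
#'
#' @param iset An `interaction_set`.
#' @param path Output path.
#' @export
write_interactions <- function(iset, path) {
  bins <- make_bins(iset$layout, iset$bin_size)
  x <- iset$interactions
  out <- data.frame(
    chrom_a = bins$chrom[x$bin_a + 1L], start_a = bins$start[x$bin_a + 1L],
    chrom_b = bins$chrom[x$bin_b + 1L], start_b = bins$start[x$bin_b + 1L],
    n = x$n, is_inter = x$is_inter
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
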