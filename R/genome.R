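#' Genome layout: ordered chromosomes with lengths
#'
#' The coordinate system every other stage consumes. Chromosome order is
#' preserved as given (file order for [load_chrom_sizes()]); all internal
#' coordinates are 0-based, half-open.
#'
#' @param chrom Character vector of unique, non-empty chromosome names.
#' @param length Numeric vector of chromosome lengths in base pairs (>= 1).
#' @return An object of class `genome_layout`: a list with elements `chrom`
#'   and `length`.
#' @examples
#' genome_layout(c("chrI", "chrII"), c(2500, 1000))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (base::length(chrom) == 0L) stopf("genome layout needs at least one chromosome")
  if (base::length(chrom) != base::length(length)) {
    stopf("chrom and length differ in length")
  }
  if (anyNA(chrom) || any(!nzchar(chrom))) stopf("chromosome names must be non-empty")
  if (anyDuplicated(chrom)) {
    stopf("duplicate chromosome name: %s", chrom[duplicated(chrom)][1L])
  }
  if (anyNA(length) || any(length < 1) || any(length != floor(length))) {
    stopf("chromosome lengths must be positive integers")
  }
  structure(list(chrom = chrom, length = length), class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf(
    "<genome_layout> %d chromosomes, %.0f bp total\n",
    length(x$chrom), sum(x$length)
  ))
  invisible(x)
}

#' Read a UCSC-style chrom.sizes file
#'
#' Two tab-separated columns: chromosome name and length. File order is
#' preserved as the chromosome order of the layout.
#'
#' @param path Path to the chrom.sizes file.
#' @return A [genome_layout()].
#' @export
load_chrom_sizes <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  if (!any(keep)) stopf("chrom.sizes file '%s' is empty", path)
  idx <- which(keep)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 2L)) {
    stopf("chrom.sizes line %d: expected two tab-separated fields", idx[nfield < 2L][1L])
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  len_str <- vapply(parts, `[[`, "", 2L)
  len <- suppressWarnings(as.numeric(len_str))
  bad <- is.na(len) | len < 1 | len != floor(len)
  if (any(bad)) {
    stopf("chrom.sizes line %d: invalid length '%s'", idx[bad][1L], len_str[bad][1L])
  }
  if (anyDuplicated(chrom)) {
    d <- which(duplicated(chrom))[1L]
    stopf("chrom.sizes line %d: duplicate chromosome '%s'", idx[d], chrom[d])
  }
  genome_layout(chrom, len)
}

# Number of fixed-width bins on each chromosome, and the 0-based global index
# at which each chromosome's bins start.
bin_offsets <- function(layout, bin_size) {
  nb <- ceiling(layout$length / bin_size)
  list(n_bins = nb, offset = cumsum(c(0, nb[-length(nb)])), total = sum(nb))
}

#' Tile a genome into fixed-width bins
#'
#' Each chromosome is tiled with non-overlapping half-open `[start, end)`
#' windows of `bin_size` bp; the trailing window of a chromosome may be
#' shorter. Bins carry a dense 0-based `global_index` increasing in
#' (chromosome order, start).
#'
#' @param layout A [genome_layout()].
#' @param bin_size Bin width in bp (default 1000, i.e. the 1-kb segments used
#'   throughout the pipeline).
#' @return A data.frame with columns `chrom`, `start`, `end`, `global_index`.
#' @examples
#' make_bins(genome_layout("chrI", 2500), 1000)
#' @export
make_bins <- function(layout, bin_size = 1000) {
  stopifnot(inherits(layout, "genome_layout"))
  if (bin_size < 1) stopf("bin_size must be >= 1")
  off <- bin_offsets(layout, bin_size)
  pieces <- lapply(seq_along(layout$chrom), function(i) {
    starts <- seq(0, layout$length[i] - 1, by = bin_size)
    data.frame(
      chrom = layout$chrom[i],
      start = starts,
      end = pmin(starts + bin_size, layout$length[i]),
      global_index = off$offset[i] + seq_along(starts) - 1,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, pieces)
}

#' Locate the bin containing a genomic position
#'
#' @param layout A [genome_layout()].
#' @param chrom Chromosome name(s).
#' @param pos 0-based position(s); must satisfy `0 <= pos < length(chrom)`.
#' @param bin_size Bin width in bp.
#' @return Integer vector of 0-based global bin indices.
#' @export
locate_bin <- function(layout, chrom, pos, bin_size = 1000) {
  stopifnot(inherits(layout, "genome_layout"))
  ci <- match(chrom, layout$chrom)
  if (anyNA(ci)) {
    stopf("unknown chromosome '%s'", chrom[is.na(ci)][1L])
  }
  bad <- pos < 0 | pos >= layout$length[ci]
  if (any(bad)) {
    stopf(
      "position %.0f out of range for chromosome '%s' (length %.0f)",
      pos[bad][1L], chrom[bad][1L], layout$length[ci][bad][1L]
    )
  }
  off <- bin_offsets(layout, bin_size)
  as.integer(off$offset[ci] + pos %/% bin_size)
}
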