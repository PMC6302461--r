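# Budding-yeast-like chromosome lengths (bp), 16 chromosomes, ~12.1 Mb.
yeast_like_lengths <- function() {
  c(
    230218, 813184, 316620, 1531933, 576874, 270161, 1090940, 562643,
    439888, 745751, 666816, 1078177, 924431, 784333, 1091291, 948066
  )
}

#' Configuration of the synthetic contact / binding-site study
#'
#' Defaults emulate the statistical structure of a yeast Hi-C + conserved
#' TF-map study: 16 chromosomes totaling ~12 Mb cut into 1-kb bins; a
#' restricted universe of ~3,500 interacting 1-kb fragments; 50,000 contacts
#' with a heavy-tailed read-count distribution (geometric tail on `n - 6`
#' calibrated so ~50% of interactions carry at most 10 reads); ~20%
#' intra-chromosomal contacts; 100 factors with 200 sites each, of which 10
#' "planted" factors bind bins with probability increasing in the bin's
#' interaction intensity (log-linear link with slope `b1`).
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_lengths Chromosome lengths in bp.
#' @param bin_size Bin width in bp.
#' @param n_interactions Number of contact draws before duplicate merging.
#' @param n_active_bins Size of the interacting-fragment universe.
#' @param intra_frac Fraction of contacts drawn intra-chromosomally.
#' @param count_model `"geometric"` (default) or `"powerlaw"` tail for the
#'   read counts.
#' @param geom_prob Geometric success parameter; the default puts half the
#'   mass at `n <= 10`.
#' @param power_exponent Exponent of the power-law alternative.
#' @param count_cap Upper cap of the power-law support.
#' @param min_count Minimum read count emitted (6: the pipeline's noise floor).
#' @param n_tfs Number of factors.
#' @param n_planted Number of planted (intensity-linked) factors.
#' @param sites_per_tf Binding sites per factor.
#' @param site_width Width of each site in bp.
#' @param b0,b1 Intercept and slope of the planted log-linear link between a
#'   bin's interaction intensity and its binding odds; `b1 = 0` reduces
#'   planted factors to the null.
#' @param seed Master seed; every simulation output is a pure function of
#'   the configuration including this seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 16,
                       chrom_lengths = yeast_like_lengths(),
                       bin_size = 1000,
                       n_interactions = 50000,
                       n_active_bins = 3500,
                       intra_frac = 0.2,
                       count_model = c("geometric", "powerlaw"),
                       geom_prob = 1 - 0.5^(1 / 5),
                       power_exponent = 2.5,
                       count_cap = 500,
                       min_count = 6,
                       n_tfs = 100,
                       n_planted = 10,
                       sites_per_tf = 200,
                       site_width = 10,
                       b0 = 0,
                       b1 = 2,
                       seed = 1L) {
  count_model <- match.arg(count_model)
  if (length(chrom_lengths) != n_chrom) {
    stopf("chrom_lengths must have n_chrom = %d entries", n_chrom)
  }
  if (n_planted >= n_tfs) stopf("n_planted must be < n_tfs")
  if (b1 < 0) stopf("b1 must be >= 0")
  if (intra_frac < 0 || intra_frac >= 1) stopf("intra_frac must be in [0, 1)")
  cfg <- list(
    n_chrom = n_chrom, chrom_lengths = chrom_lengths, bin_size = bin_size,
    n_interactions = n_interactions, n_active_bins = n_active_bins,
    intra_frac = intra_frac, count_model = count_model,
    geom_prob = geom_prob, power_exponent = power_exponent,
    count_cap = count_cap, min_count = min_count,
    n_tfs = n_tfs, n_planted = n_planted, sites_per_tf = sites_per_tf,
    site_width = site_width, b0 = b0, b1 = b1, seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

tf_names <- function(cfg) sprintf("TF%03d", seq_len(cfg$n_tfs))

#' Simulate the genome layout
#'
#' @param cfg A [sim_config()].
#' @return A [genome_layout()] with chromosomes `chrI`, `chrII`, ...
#' @export
simulate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  roman <- as.character(utils::as.roman(seq_len(cfg$n_chrom)))
  genome_layout(paste0("chr", roman), cfg$chrom_lengths)
}

draw_counts <- function(cfg, m) {
  if (cfg$count_model == "geometric") {
    cfg$min_count + stats::rgeom(m, prob = cfg$geom_prob)
  } else {
    support <- 0:(cfg$count_cap - cfg$min_count)
    prob <- (support + 1)^(-cfg$power_exponent)
    cfg$min_count + sample(support, m, replace = TRUE, prob = prob)
  }
}

#' Simulate bin-pair interactions
#'
#' A fixed universe of `n_active_bins` "interacting fragments" is sampled
#' uniformly over the genome's bins; contacts are then drawn uniformly over
#' inter-chromosomal pairs of active bins (plus an `intra_frac` share of
#' intra-chromosomal pairs), given heavy-tailed read counts with minimum
#' `min_count`, and duplicate pairs are merged by summing counts.
#'
#' @param layout A [genome_layout()] (from [simulate_genome()]).
#' @param cfg A [sim_config()].
#' @return An `interaction_set`.
#' @export
simulate_interactions <- function(layout, cfg) {
  stopifnot(inherits(layout, "genome_layout"), inherits(cfg, "sim_config"))
  off <- bin_offsets(layout, cfg$bin_size)
  if (cfg$n_active_bins > off$total) {
    stopf("n_active_bins (%d) exceeds bin count (%d)", cfg$n_active_bins, off$total)
  }
  with_seed(cfg$seed, {
    active <- sort(sample.int(off$total, cfg$n_active_bins) - 1L)
    chrom_of <- findInterval(active, off$offset) # chromosome index per active bin
    per_chrom <- tabulate(chrom_of, nbins = cfg$n_chrom)
    n_intra_pairs <- sum(choose(per_chrom, 2))
    n_inter_pairs <- choose(cfg$n_active_bins, 2) - n_intra_pairs
    m_intra <- round(cfg$n_interactions * cfg$intra_frac)
    m_inter <- cfg$n_interactions - m_intra
    if (m_inter > n_inter_pairs || m_intra > n_intra_pairs) {
      stopf("n_interactions exceeds the number of distinct available bin pairs")
    }
    draw_pairs <- function(m, want_inter) {
      a <- integer(0); b <- integer(0)
      while (length(a) < m) {
        need <- ceiling((m - length(a)) * 1.6) + 10L
        i <- sample.int(cfg$n_active_bins, need, replace = TRUE)
        j <- sample.int(cfg$n_active_bins, need, replace = TRUE)
        ok <- if (want_inter) chrom_of[i] != chrom_of[j] else
          (chrom_of[i] == chrom_of[j] & i != j)
        a <- c(a, active[i[ok]]); b <- c(b, active[j[ok]])
      }
      list(a = a[seq_len(m)], b = b[seq_len(m)])
    }
    pi_ <- draw_pairs(m_inter, TRUE)
    pa <- if (m_intra > 0) draw_pairs(m_intra, FALSE) else list(a = integer(), b = integer())
    bin_a <- pmin(c(pi_$a, pa$a), c(pi_$b, pa$b))
    bin_b <- pmax(c(pi_$a, pa$a), c(pi_$b, pa$b))
    cnt <- draw_counts(cfg, length(bin_a))
    key <- paste(bin_a, bin_b)
    agg <- rowsum(cnt, key, reorder = FALSE)
    first <- !duplicated(key)
    ua <- bin_a[first]; ub <- bin_b[first]
    n_agg <- as.numeric(agg[, 1L])
    o <- order(ua, ub)
    ca <- findInterval(ua[o], off$offset)
    cb <- findInterval(ub[o], off$offset)
    inter <- data.frame(
      bin_a = ua[o], bin_b = ub[o], n = n_agg[o], is_inter = ca != cb
    )
    new_interaction_set(inter, layout, cfg$bin_size, list(
      simulated = TRUE, seed = cfg$seed,
      draws = cfg$n_interactions, merged_duplicates = cfg$n_interactions - nrow(inter)
    ))
  })
}

#' Simulate binding sites with planted intensity-linked factors
#'
#' Each bin gets an intensity score `s = log(1 + max n)` over the
#' interactions touching it (0 for untouched bins). Null factors place their
#' sites uniformly at random over all bins; planted factors sample bins
#' without replacement with probability proportional to `exp(b0 + b1 * s)`,
#' so both bins of a strong interaction tend to be bound — the dependence
#' the enrichment methods are built to detect. Site intervals are placed
#' inside the chosen bin.
#'
#' @param layout A [genome_layout()].
#' @param iset The `interaction_set` supplying the intensity (typically the
#'   filtered inter-chromosomal set the pipeline analyses).
#' @param cfg A [sim_config()].
#' @return A list with `records` (binding-site data.frame as from
#'   [read_tfbs()]) and `truth` (per factor: `planted` flag and true `b1`).
#' @export
simulate_tfbs <- function(layout, iset, cfg) {
  stopifnot(
    inherits(layout, "genome_layout"), inherits(iset, "interaction_set"),
    inherits(cfg, "sim_config")
  )
  off <- bin_offsets(layout, cfg$bin_size)
  if (cfg$sites_per_tf > off$total) {
    stopf("sites_per_tf (%d) exceeds bin count (%d)", cfg$sites_per_tf, off$total)
  }
  x <- iset$interactions
  max_n <- numeric(off$total)
  for (col in c("bin_a", "bin_b")) {
    agg <- tapply(x$n, x[[col]], max)
    idx <- as.integer(names(agg)) + 1L
    max_n[idx] <- pmax(max_n[idx], as.numeric(agg))
  }
  s <- log1p(max_n)
  w_planted <- exp(cfg$b0 + cfg$b1 * s)
  tfs <- tf_names(cfg)
  planted <- tfs[seq_len(cfg$n_planted)]
  bins <- make_bins(layout, cfg$bin_size)
  with_seed(cfg$seed + 1L, {
    rec <- lapply(tfs, function(tf) {
      prob <- if (tf %in% planted) w_planted else rep(1, off$total)
      chosen <- sample.int(off$total, cfg$sites_per_tf, prob = prob) - 1L
      chosen <- sort(chosen)
      width <- pmin(cfg$site_width, bins$end[chosen + 1L] - bins$start[chosen + 1L])
      room <- (bins$end[chosen + 1L] - bins$start[chosen + 1L]) - width
      offset <- floor(stats::runif(length(chosen)) * (room + 1))
      start <- bins$start[chosen + 1L] + offset
      data.frame(
        tf = tf, chrom = bins$chrom[chosen + 1L],
        start = as.integer(start), end = as.integer(start + width),
        stringsAsFactors = FALSE
      )
    })
    records <- do.call(rbind, rec)
    rownames(records) <- NULL
    truth <- data.frame(
      tf = tfs, planted = tfs %in% planted,
      b1 = ifelse(tfs %in% planted, cfg$b1, 0),
      stringsAsFactors = FALSE
    )
    list(records = records, truth = truth)
  })
}

#' Write a complete synthetic fixture to disk
#'
#' Emits `chrom.sizes`, `contacts.tsv` (1-based five-column contact list),
#' `tfbs.bed` (BED4) and `truth.json` (the configuration plus the planted
#' flags) into `dir`. Binding sites are planted against the filtered
#' inter-chromosomal interaction set, i.e. the set the pipeline analyses.
#' Re-reading the files through [load_chrom_sizes()], [read_contacts()] /
#' [bin_contacts()] and [read_tfbs()] / [mark_bins()] reproduces the
#' in-memory objects exactly.
#'
#' @param dir Output directory (created if missing).
#' @param cfg A [sim_config()].
#' @return (Invisibly) a list with the generated `layout`, raw `iset`,
#'   filtered inter-chromosomal set `iset_analysis`, `tfbs` records, `truth`,
#'   and the file paths.
#' @export
write_fixture <- function(dir, cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  layout <- simulate_genome(cfg)
  iset <- simulate_interactions(layout, cfg)
  iset_analysis <- subset_interactions(
    filter_interactions(iset, min_reads = cfg$min_count), "inter"
  )
  sim <- simulate_tfbs(layout, iset_analysis, cfg)

  paths <- list(
    chrom_sizes = file.path(dir, "chrom.sizes"),
    contacts = file.path(dir, "contacts.tsv"),
    tfbs = file.path(dir, "tfbs.bed"),
    truth = file.path(dir, "truth.json")
  )
  writeLines(
    paste(layout$chrom, format(layout$length, scientific = FALSE, trim = TRUE),
      sep = "\t"
    ),
    paths$chrom_sizes
  )
  bins <- make_bins(layout, cfg$bin_size)
  x <- iset$interactions
  contacts <- data.frame(
    chrom1 = bins$chrom[x$bin_a + 1L], pos1 = bins$start[x$bin_a + 1L] + 1,
    chrom2 = bins$chrom[x$bin_b + 1L], pos2 = bins$start[x$bin_b + 1L] + 1,
    count = x$n
  )
  utils::write.table(contacts, paths$contacts,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  bed <- sim$records
  utils::write.table(
    data.frame(bed$chrom, bed$start, bed$end, bed$tf),
    paths$tfbs,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  jsonlite::write_json(
    list(config = unclass(cfg), truth = sim$truth),
    paths$truth,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(
    layout = layout, iset = iset, iset_analysis = iset_analysis,
    tfbs = sim$records, truth = sim$truth, paths = paths
  ))
}
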