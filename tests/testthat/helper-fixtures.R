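# Builders and independent brute-force oracles shared across the suite.

# An interaction set constructed directly from bin pairs (bypassing file IO).
make_iset <- function(bin_a, bin_b, n, layout, bin_size = 1000) {
  bins <- make_bins(layout, bin_size)
  inter <- data.frame(
    bin_a = bin_a, bin_b = bin_b, n = as.numeric(n),
    is_inter = bins$chrom[bin_a + 1L] != bins$chrom[bin_b + 1L]
  )
  tfhic:::new_interaction_set(inter, layout, bin_size, list(test = TRUE))
}

make_map <- function(bins_per_tf, layout, bin_size = 1000) {
  off <- tfhic:::bin_offsets(layout, bin_size)
  structure(
    lapply(bins_per_tf, function(b) sort(unique(as.integer(b)))),
    class = "tf_binding_map", bin_size = bin_size, n_bins = off$total
  )
}

# A layout with plenty of room for randomly generated instances.
big_layout <- function(n_chrom = 4, chrom_len = 50000) {
  genome_layout(paste0("chr", seq_len(n_chrom)), rep(chrom_len, n_chrom))
}

# Random labelled instance: n interactions over distinct bin pairs, k TFs.
random_instance <- function(n_int, n_tf, seed, max_reads = 80) {
  set.seed(seed)
  layout <- big_layout()
  total_bins <- sum(ceiling(layout$length / 1000))
  bin_a <- sample.int(total_bins - 1L, n_int, replace = TRUE) - 1L
  bin_b <- bin_a + sample.int(20, n_int, replace = TRUE)
  bin_b <- pmin(bin_b, total_bins - 1L)
  keep <- !duplicated(paste(bin_a, bin_b)) & bin_a < bin_b
  bin_a <- bin_a[keep]; bin_b <- bin_b[keep]
  n <- sample(6:max_reads, length(bin_a), replace = TRUE)
  iset <- make_iset(bin_a, bin_b, n, layout)
  map <- make_map(
    stats::setNames(
      lapply(seq_len(n_tf), function(i) {
        sample.int(total_bins, sample(5:60, 1)) - 1L
      }),
      sprintf("TF%02d", seq_len(n_tf))
    ),
    layout
  )
  list(iset = iset, map = map, lab = label_interactions(iset, map))
}

# Brute-force per-interaction labelling (oracle for label_interactions).
brute_labels <- function(iset, map) {
  x <- iset$interactions
  out <- matrix(FALSE, nrow(x), length(map), dimnames = list(NULL, names(map)))
  for (i in seq_len(nrow(x))) {
    for (j in seq_along(map)) {
      out[i, j] <- (x$bin_a[i] %in% map[[j]]) || (x$bin_b[i] %in% map[[j]])
    }
  }
  out
}

# Brute-force ratio-curve recount (oracle for ratio_curves).
brute_ratio <- function(labels, T_grid) {
  tfs <- colnames(labels$labels)
  do.call(rbind, lapply(tfs, function(tf) {
    do.call(rbind, lapply(T_grid, function(Tt) {
      inA <- which(labels$n >= Tt)
      ab <- sum(labels$labels[inA, tf])
      data.frame(
        tf = tf, T = Tt, size_A = length(inA), size_AB = ab,
        defined = length(inA) > 0,
        ratio = if (length(inA) > 0) ab / length(inA) else NA_real_,
        stringsAsFactors = FALSE
      )
    }))
  }))
}

# Chi-square oracle via expected counts, the long way round.
brute_chisq <- function(a11, a12, a21, a22) {
  O <- matrix(c(a11, a12, a21, a22), 2, 2)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

# Scaled-down planted study for unit tests.
small_sim <- function(seed = 5, b1 = 2, ...) {
  sim_config(
    n_interactions = 4000, n_active_bins = 800, n_tfs = 30, n_planted = 5,
    sites_per_tf = 80, b1 = b1, seed = seed, ...
  )
}

sim_curves <- function(cfg) {
  layout <- simulate_genome(cfg)
  iset <- subset_interactions(
    filter_interactions(simulate_interactions(layout, cfg)), "inter"
  )
  sim <- simulate_tfbs(layout, iset, cfg)
  map <- mark_bins(sim$records, layout, cfg$bin_size, tfs = sim$truth$tf)
  labels <- label_interactions(iset, map)
  list(
    layout = layout, iset = iset, truth = sim$truth, map = map,
    labels = labels, curves = ratio_curves(labels)
  )
}

# The full-scale study conditions used by the acceptance checks, computed at
# most once per test run and shared between blocks.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_run <- function() {
  if (is.null(.acceptance_cache$runA)) {
    .acceptance_cache$dirA <- file.path(tempdir(), "tfhic-bundle-A")
    .acceptance_cache$runA <- run_pipeline(
      list(sim = sim_config(seed = 1), seed = 1),
      out_dir = .acceptance_cache$dirA, quiet = TRUE
    )
  }
  list(run = .acceptance_cache$runA, dir = .acceptance_cache$dirA)
}
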