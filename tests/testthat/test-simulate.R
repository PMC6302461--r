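test_that("the simulated genome matches its configuration deterministically", {
  cfg <- sim_config(n_chrom = 2, chrom_lengths = c(10000, 5000))
  lay <- simulate_genome(cfg)
  expect_identical(lay$length, c(10000, 5000))
  expect_identical(simulate_genome(cfg), lay)
  expect_identical(length(simulate_genome(sim_config())$chrom), 16L)
  expect_error(sim_config(n_chrom = 3, chrom_lengths = c(1, 2)), "n_chrom")
  expect_error(sim_config(n_planted = 10, n_tfs = 10), "n_planted")
})

test_that("simulated interactions have the intended heavy-tailed shape", {
  cfg <- sim_config(n_interactions = 10000, seed = 1)
  lay <- simulate_genome(cfg)
  iset <- simulate_interactions(lay, cfg)
  n <- iset$interactions$n
  expect_true(all(n >= 6))
  expect_lte(stats::median(n), 12)
  expect_gte(max(n), 60)
  # roughly half of the mass at or below 10 reads
  expect_gt(mean(n <= 10), 0.35)
  expect_lt(mean(n <= 10), 0.65)
  # determinism and seed sensitivity
  expect_identical(simulate_interactions(lay, cfg), iset)
  cfg2 <- sim_config(n_interactions = 10000, seed = 2)
  expect_false(identical(simulate_interactions(lay, cfg2)$interactions, iset$interactions))
  # intra fraction 0 leaves only inter-chromosomal pairs
  cfg0 <- sim_config(intra_frac = 0, n_interactions = 3000, seed = 3)
  expect_true(all(simulate_interactions(simulate_genome(cfg0), cfg0)$interactions$is_inter))
  # more pairs than the universe allows is an error
  tiny <- sim_config(
    n_chrom = 2, chrom_lengths = c(3000, 3000), n_active_bins = 4,
    n_interactions = 100
  )
  expect_error(simulate_interactions(simulate_genome(tiny), tiny), "distinct")
})

test_that("planted factors gain intensity-linked binding; b1 = 0 turns it off", {
  cfg <- small_sim(seed = 14, b1 = 2)
  sc <- sim_curves(cfg)
  d <- as.data.frame(sc$curves)
  planted <- sc$truth$tf[sc$truth$planted]
  r_lo <- d$ratio[d$T == 7][match(planted, attr(sc$curves, "tfs"))]
  r_hi <- d$ratio[d$T == 40][match(planted, attr(sc$curves, "tfs"))]
  expect_gte(sum(r_hi > r_lo), length(planted) - 1L)

  # with b1 = 0 planted and null factors are exchangeable: slopes comparable
  sc0 <- sim_curves(small_sim(seed = 14, b1 = 0))
  d0 <- as.data.frame(sc0$curves)
  d0 <- d0[d0$defined & d0$T <= 40, ]
  slopes <- vapply(split(d0, d0$tf), function(s) {
    unname(stats::coef(stats::lm(ratio ~ T, data = s))[2L])
  }, numeric(1))
  pl <- sc0$truth$planted[match(names(slopes), sc0$truth$tf)]
  expect_lt(
    abs(mean(slopes[pl]) - mean(slopes[!pl])),
    3 * stats::sd(slopes) * sqrt(1 / sum(pl) + 1 / sum(!pl))
  )
  # determinism of the site generator
  lay <- simulate_genome(cfg)
  iset <- sc$iset
  expect_identical(simulate_tfbs(lay, iset, cfg), simulate_tfbs(lay, iset, cfg))
})

test_that("planted and null ratio slopes separate for b1 >= 1 across seeds", {
  diffs <- vapply(1:6, function(s) {
    sc <- sim_curves(small_sim(seed = 500 + s, b1 = 1))
    d <- as.data.frame(sc$curves)
    d <- d[d$defined & d$T <= 40, ]
    slopes <- vapply(split(d, d$tf), function(x) {
      unname(stats::coef(stats::lm(ratio ~ T, data = x))[2L])
    }, numeric(1))
    pl <- sc$truth$planted[match(names(slopes), sc$truth$tf)]
    mean(slopes[pl]) - mean(slopes[!pl])
  }, numeric(1))
  expect_true(all(diffs > 0))
})

test_that("fixtures round-trip bit-exactly through the readers", {
  cfg <- sim_config(
    n_interactions = 2000, n_active_bins = 500, n_tfs = 10, n_planted = 2,
    sites_per_tf = 40, seed = 9
  )
  dir <- withr::local_tempdir()
  fx <- write_fixture(dir, cfg)
  expect_setequal(
    basename(unlist(fx$paths)),
    c("chrom.sizes", "contacts.tsv", "tfbs.bed", "truth.json")
  )
  lay2 <- load_chrom_sizes(fx$paths$chrom_sizes)
  expect_identical(lay2, fx$layout)
  iset2 <- bin_contacts(read_contacts(fx$paths$contacts, lay2), lay2, cfg$bin_size)
  expect_identical(iset2$interactions, fx$iset$interactions)
  rec2 <- read_tfbs(fx$paths$tfbs, lay2)
  expect_identical(rec2, fx$tfbs)
  expect_identical(
    mark_bins(rec2, lay2, cfg$bin_size),
    mark_bins(fx$tfbs, fx$layout, cfg$bin_size)
  )
  # ground truth embeds the regenerating configuration
  truth <- jsonlite::read_json(fx$paths$truth, simplifyVector = TRUE)
  expect_identical(as.integer(truth$config$seed), cfg$seed)
  expect_identical(sum(truth$truth$planted), 2L)
  # a different seed produces different contacts
  dir2 <- withr::local_tempdir()
  cfgb <- sim_config(
    n_interactions = 2000, n_active_bins = 500, n_tfs = 10, n_planted = 2,
    sites_per_tf = 40, seed = 10
  )
  fx2 <- write_fixture(dir2, cfgb)
  expect_false(identical(
    readLines(fx$paths$contacts), readLines(fx2$paths$contacts)
  ))
})
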