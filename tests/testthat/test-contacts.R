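layout2 <- genome_layout(c("chrI", "chrII"), c(5000, 4000))

test_that("contact parsing validates against the layout with line numbers", {
  ok <- withr::local_tempfile(lines = c(
    "# a comment", "chrI\t500\tchrII\t700\t8"
  ))
  rec <- read_contacts(ok, layout2)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$pos1, 499) # converted to 0-based
  expect_identical(rec$line, 2L)

  expect_error(
    read_contacts(
      withr::local_tempfile(lines = "chrX\t1\tchrII\t1\t5"), layout2
    ),
    "line 1.*unknown chromosome"
  )
  expect_error(
    read_contacts(
      withr::local_tempfile(lines = c("chrI\t1\tchrII\t1\t5", "chrI\t1\tchrII\t1\t0")),
      layout2
    ),
    "line 2.*count"
  )
  expect_error(
    read_contacts(withr::local_tempfile(lines = "chrI\t1\tchrII\t5"), layout2),
    "5 tab-separated"
  )
  expect_error(
    read_contacts(withr::local_tempfile(lines = "chrI\t5001\tchrII\t1\t5"), layout2),
    "out of chromosome bounds"
  )
})

test_that("binning aggregates duplicates, canonicalizes, and drops same-bin ends", {
  lines <- c(
    "chrI\t500\tchrII\t700\t3",
    "chrII\t800\tchrI\t600\t4", # same canonical pair, reversed order
    "chrI\t100\tchrI\t900\t7" # both ends in bin 0
  )
  rec <- read_contacts(withr::local_tempfile(lines = lines), layout2)
  expect_message(iset <- bin_contacts(rec, layout2, 1000), "same-bin")
  expect_identical(nrow(iset$interactions), 1L)
  expect_identical(iset$interactions$n, 7)
  expect_true(iset$interactions$bin_a < iset$interactions$bin_b)
  # reads conserved: in = out + dropped
  expect_equal(
    sum(rec$count),
    sum(iset$interactions$n) + iset$provenance$same_bin_reads_dropped
  )
})

test_that("filters implement the separation and read-count rules", {
  # bins: chrI = 0..4, chrII = 5..8
  iset <- make_iset(
    bin_a = c(0L, 0L, 1L, 0L, 2L),
    bin_b = c(1L, 2L, 6L, 5L, 4L),
    n = c(50, 9, 5, 6, 12),
    layout2
  )
  f <- filter_interactions(iset)
  # adjacent intra pair dropped despite n = 50; inter n = 5 dropped; n = 6 kept
  expect_identical(f$interactions$bin_a, c(0L, 0L, 2L))
  expect_identical(f$interactions$n, c(9, 6, 12))
  expect_identical(f$provenance$removed_distance, 1L)
  expect_identical(f$provenance$removed_low_reads, 1L)
  # inter-chromosomal pairs are never removed by the distance rule, even when
  # their global indices are adjacent (bins 4 and 5 span the chromosome break)
  adj <- make_iset(4L, 5L, 6, layout2)
  expect_identical(nrow(filter_interactions(adj)$interactions), 1L)
  # idempotence
  f2 <- filter_interactions(f)
  expect_identical(f2$interactions, f$interactions)
  expect_error(filter_interactions(iset, min_reads = 0), "min_reads")
  expect_error(filter_interactions(iset, min_separation_bins = 0), "min_separation")
})

test_that("subsetting by inter/intra is exact and commutes with filtering", {
  set.seed(71)
  layout <- big_layout()
  total_bins <- sum(ceiling(layout$length / 1000))
  a <- sample.int(total_bins - 5L, 300, replace = TRUE) - 1L
  b <- pmin(a + sample.int(60, 300, replace = TRUE), total_bins - 1L)
  ok <- a < b & !duplicated(paste(a, b))
  iset <- make_iset(a[ok], b[ok], sample(1:40, sum(ok), replace = TRUE), layout)

  inter <- subset_interactions(iset, "inter")
  expect_true(all(inter$interactions$is_inter))
  expect_identical(subset_interactions(iset, "all")$interactions, iset$interactions)
  only_inter <- subset_interactions(subset_interactions(iset, "inter"), "intra")
  expect_identical(nrow(only_inter$interactions), 0L)

  for (which in c("inter", "intra")) {
    path1 <- subset_interactions(filter_interactions(iset), which)
    path2 <- filter_interactions(subset_interactions(iset, which))
    expect_identical(path1$interactions, path2$interactions)
  }
})

test_that("count_distribution matches direct counting", {
  iset <- make_iset(c(0L, 0L, 1L), c(5L, 6L, 7L), c(6, 6, 10), layout2)
  d <- count_distribution(iset)
  expect_identical(d$n, c(6, 10))
  expect_identical(d$count, c(2L, 1L))
  expect_equal(d$cum_share, c(2 / 3, 1))
  expect_identical(nrow(count_distribution(make_iset(integer(), integer(), numeric(), layout2))), 0L)
})
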