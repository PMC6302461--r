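layout8 <- genome_layout("chrI", 8000)

hand_labels <- function() {
  iset <- make_iset(c(0L, 2L, 4L, 6L), c(1L, 3L, 5L, 7L), c(6, 10, 20, 50), layout8)
  map <- make_map(list(tfA = c(4L, 6L), all_pos = 0:7, none = integer()), layout8)
  label_interactions(iset, map)
}

test_that("contingency cells come from exact counting", {
  lab <- hand_labels()
  ct <- contingency(lab, "tfA", 15)
  expect_identical(
    c(ct$a11, ct$a12, ct$a21, ct$a22),
    c(2L, 0L, 0L, 2L)
  )
  # T above the maximum read count empties the A margin
  hi <- contingency(lab, "tfA", 100)
  expect_identical(hi$a11 + hi$a21, 0L)
  expect_false(chisq_test(hi)$testable)
  # all interactions positive empties the complement-of-B margin
  ap <- contingency(lab, "all_pos", 15)
  expect_identical(ap$a21 + ap$a22, 0L)
  expect_false(chisq_test(ap)$testable)
  expect_error(contingency(lab, "nope", 15), "unknown factor")
})

test_that("chi-square statistic matches its closed form and stats::chisq.test", {
  expect_equal(chisq_test(list(a11 = 5, a12 = 5, a21 = 5, a22 = 5))$statistic, 0)
  expect_equal(chisq_test(list(a11 = 5, a12 = 5, a21 = 5, a22 = 5))$p, 1)
  r <- chisq_test(list(a11 = 10, a12 = 20, a21 = 30, a22 = 40))
  expect_equal(r$statistic, brute_chisq(10, 20, 30, 40), tolerance = 1e-12)
  expect_equal(r$statistic, 0.7936508, tolerance = 1e-6)
  # symmetry under joint row/column swap
  expect_equal(
    chisq_test(list(a11 = 0, a12 = 10, a21 = 10, a22 = 0))$statistic,
    chisq_test(list(a11 = 10, a12 = 0, a21 = 0, a22 = 10))$statistic
  )
  # Yates correction agrees with R's default 2x2 behaviour
  set.seed(12)
  for (i in 1:25) {
    tab <- matrix(sample(1:50, 4, replace = TRUE), 2)
    mine <- chisq_test(list(a11 = tab[1], a12 = tab[2], a21 = tab[3], a22 = tab[4]),
      yates = TRUE
    )
    ref <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("the threshold scan counts cells exactly and flags untestable ones", {
  lab <- hand_labels()
  sc <- chisq_scan(lab, T_min = 7, T_max = 60)
  cells <- sc$cells
  # every cell sums to the interaction count
  expect_true(all(cells$a11 + cells$a12 + cells$a21 + cells$a22 == 4))
  # cells with T above max reads are untestable, as are saturated factors
  expect_true(all(!cells$testable[cells$T > 50]))
  expect_true(all(!cells$testable[cells$tf == "all_pos"]))
  expect_true(all(!cells$testable[cells$tf == "none"]))
  # untestable cells carry no p-value and are excluded from the family
  expect_true(all(is.na(cells$p[!cells$testable])))
  expect_identical(sc$m, sum(cells$testable))
  # adjusted p = min(1, p * m)
  ok <- cells$testable
  expect_equal(cells$p_adj[ok], pmin(1, cells$p[ok] * sc$m))
  expect_error(chisq_scan(lab, T_min = 45, T_max = 7), "T_min")
})

test_that("scan results are invariant to interaction order", {
  inst <- random_instance(n_int = 200, n_tf = 5, seed = 77)
  sc1 <- chisq_scan(inst$lab)
  set.seed(1)
  perm <- sample(nrow(inst$iset$interactions))
  x <- inst$iset$interactions[perm, , drop = FALSE]
  iset2 <- make_iset(x$bin_a, x$bin_b, x$n, inst$iset$layout)
  sc2 <- chisq_scan(label_interactions(iset2, inst$map))
  expect_identical(sc1$cells, sc2$cells)
})

test_that("significant factor calling orders by hit count then name", {
  lab <- hand_labels()
  # alpha = 0: nothing can be significant
  sc <- chisq_scan(lab)
  expect_identical(significant_tfs(sc, alpha = 0), character())

  # planted small simulation: strong factors reach Bonferroni significance
  sc2 <- sim_curves(small_sim(seed = 5))
  scan2 <- chisq_scan(sc2$labels)
  sig <- significant_tfs(scan2)
  expect_gt(length(sig), 0)
  counts <- scan2$summary$n_adj_sig[match(sig, scan2$summary$tf)]
  expect_true(all(diff(counts) <= 0))
  ties <- split(sig, counts)
  expect_true(all(vapply(ties, function(g) !is.unsorted(g), logical(1))))
})

test_that("per-tf Bonferroni family divides by each factor's testable count", {
  inst <- random_instance(n_int = 300, n_tf = 4, seed = 13)
  g <- chisq_scan(inst$lab, family = "global")
  p <- chisq_scan(inst$lab, family = "per-tf")
  expect_identical(g$cells$p, p$cells$p)
  ok <- p$cells$testable
  m_tf <- tapply(p$cells$testable, p$cells$tf, sum)[p$cells$tf]
  expect_equal(p$cells$p_adj[ok], pmin(1, p$cells$p[ok] * as.numeric(m_tf)[ok]))
})
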