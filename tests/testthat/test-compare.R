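test_that("renumbering shifts above the breakpoint, fixes below, and inverts", {
  rn <- renumbering(after = 23, offset = -1)
  expect_equal(renumber(rn, 1:23), 1:23)
  expect_equal(renumber(rn, 24L), 23L)
  expect_equal(renumber(rn, 30L), 29L)
  inv <- invert_renumbering(rn)
  # map o inverse is the identity on reference numbers
  expect_equal(renumber(rn, renumber(inv, 1:60)), 1:60)
  # inverse o map is the identity away from the insertion point
  expect_equal(renumber(inv, renumber(rn, 25:60)), 25:60)
  # non-injective input is rejected
  expect_error(renumber(rn, c(23L, 24L)), "strictly increasing")
  expect_error(renumbering(after = c(5, 3), offset = c(1, 1)), "increasing")
})

test_that("pair categories on the 8-residue toy match exhaustive hand enumeration", {
  ts <- make_toy_structure(8, "extended")
  mask <- contact_mask(ts, 5, 2)
  dcc <- dcc_from_values(8)
  ics <- manual_ics(c(1, 4), c(5, 8))
  tab <- categorize_pairs(dcc, ics, mask = mask)

  # retained pairs: |i - j| >= 3 in an extended chain (no spatial contacts)
  expect_equal(nrow(tab), 15L)
  expect_true(all(abs(tab$res_i - tab$res_j) >= 3))
  expect_equal(sum(tab$category == "IC 1"), 1L)   # (1,4)
  expect_equal(sum(tab$category == "IC 2"), 1L)   # (5,8)
  expect_equal(sum(tab$any_ic), 5L)               # both in {1,4,5,8}
  expect_equal(sum(tab$no_ic), 4L)                # (2,6),(2,7),(3,6),(3,7)
  # partition identity
  expect_equal(sum(grepl("^IC ", tab$category)) +
                 sum(tab$category == "Not in same IC"), nrow(tab))
  # same-IC pairs are a subset of any-IC pairs and disjoint from the rest
  expect_true(all(tab$any_ic[grepl("^IC ", tab$category)]))
  expect_false(any(tab$no_ic & grepl("^IC ", tab$category)))
  # |DCC| recorded
  expect_equal(tab$abs_dcc, abs(tab$dcc))
})

test_that("empty IC set sends every retained pair to No IC", {
  dcc <- dcc_from_values(6)
  ics <- manual_ics(integer(0))
  tab <- categorize_pairs(dcc, ics)
  expect_true(all(tab$category == "Not in same IC"))
  expect_true(all(tab$no_ic))
  expect_false(any(tab$any_ic))
})

test_that("renumbering routes trajectory residues onto reference IC positions", {
  # mutant-style numbering: trajectory residues shifted up by one after 23
  dcc <- dcc_from_values(30)
  ics <- manual_ics(c(20, 23, 27))
  rn <- renumbering(after = 23, offset = -1)
  tab <- categorize_pairs(dcc, ics, renum = rn)
  # trajectory residue 24 maps to reference 23 -> pair (20, 24) is IC 1
  row <- tab[tab$res_i == 20 & tab$res_j == 24, ]
  expect_equal(row$ref_j, 23L)
  expect_equal(row$category, "IC 1")
  # trajectory residue 28 maps to reference 27
  row2 <- tab[tab$res_i == 20 & tab$res_j == 28, ]
  expect_equal(row2$category, "IC 1")
  # unmappable residues are reported
  expect_error(
    categorize_pairs(dcc, ics, renum = rn, reference_positions = 1:20),
    "unmappable")
})

test_that("the category partition identity holds on random inputs", {
  set.seed(14)
  for (rep in 1:5) {
    n <- sample(10:25, 1)
    dcc <- dcc_from_values(n)
    sets <- split(sample(n, 8), rep(1:2, each = 4))
    ics <- manual_ics(sets[[1]], sets[[2]])
    tab <- categorize_pairs(dcc, ics)
    expect_equal(sum(grepl("^IC ", tab$category)) +
                   sum(tab$category == "Not in same IC"), nrow(tab))
  }
})

test_that("Mann-Whitney U matches hand-computed and enumerated exact p-values", {
  tst <- mwu_two_sided(c(1, 2), c(3, 4))
  expect_equal(tst$U, 0)
  expect_equal(tst$p, 2 / 6)     # 2 * (1 / C(4,2))
  expect_equal(tst$method, "exact")

  # exhaustive-permutation oracle across sample sizes
  set.seed(15)
  for (n in 1:6) {
    for (m in c(n, n + 2, 8)) {
      x <- rnorm(n); y <- rnorm(m)
      got <- mwu_two_sided(x, y)
      oracle <- brute_mwu(x, y)
      expect_equal(got$U, oracle$U)
      expect_equal(got$p, oracle$p, tolerance = 1e-12)
    }
  }
  expect_error(mwu_two_sided(numeric(0), 1), "nonempty")
})

test_that("the tie-corrected normal approximation is sane for identical samples", {
  x <- rep(c(1, 2, 3), 8)
  got <- mwu_two_sided(x, x)
  expect_equal(got$U, length(x)^2 / 2)
  expect_gte(got$p, 0.99)
  # large-sample approximation close to the exact path
  set.seed(16)
  x2 <- rnorm(40); y2 <- rnorm(45)
  approx_p <- mwu_two_sided(x2, y2)$p
  ref_p <- stats::wilcox.test(x2, y2, exact = FALSE, correct = TRUE)$p.value
  expect_equal(approx_p, ref_p, tolerance = 1e-6)
})

test_that("category comparison reports means, stars, and skips empty contrasts", {
  # toy table of 8 pairs with hand arithmetic
  dcc <- dcc_from_values(8, fill = seq(0.05, 0.05 * 28, by = 0.05) *
                           rep_len(c(1, -1), 28))
  ics <- manual_ics(c(1, 4, 6))
  tab <- categorize_pairs(dcc, ics)
  cmp <- compare_categories(tab)
  same <- tab$abs_dcc[tab$category == "IC 1"]
  expect_equal(cmp$categories$mean[cmp$categories$category == "IC 1"],
               mean(same))
  expect_equal(cmp$categories$mean[cmp$categories$category == "No IC"],
               mean(tab$abs_dcc[tab$no_ic]))
  td <- tidy(cmp)
  expect_true(all(c("U", "p", "p_bh", "stars") %in% names(td)))
  expect_equal(nrow(glance(cmp)), 1L)

  # empty category -> warning, contrast skipped
  ics0 <- manual_ics(integer(0))
  tab0 <- categorize_pairs(dcc, ics0)
  expect_warning(cmp0 <- compare_categories(tab0,
                                            contrasts = list(c("IC 1", "No IC"))),
                 "empty")
  expect_equal(nrow(cmp0$tests), 0L)
})

test_that("comparison output is invariant to row order of the pair table", {
  dcc <- dcc_from_values(12)
  ics <- manual_ics(1:4, 7:10)
  tab <- categorize_pairs(dcc, ics)
  cmp1 <- compare_categories(tab)
  set.seed(17)
  tab2 <- tab[sample(nrow(tab)), ]
  cmp2 <- compare_categories(tab2)
  expect_equal(cmp1$tests, cmp2$tests)
  expect_equal(cmp1$categories, cmp2$categories)
})

test_that("all-equal |DCC| values give p near 1 under the tie-corrected test", {
  dcc <- dcc_from_values(10, fill = rep(0.4, 45))
  ics <- manual_ics(c(1, 5, 9))
  tab <- categorize_pairs(dcc, ics)
  cmp <- compare_categories(tab, contrasts = list(c("IC 1", "No IC")))
  expect_gte(cmp$tests$p[1], 0.99)
})

test_that("planted correlated motion separates IC pairs from the rest", {
  sim <- make_trajectory(n_frames = 400, n_residues = 30,
                         blocks = list(5:12), target_correlation = 0.8,
                         seed = 23)
  d <- dcc_matrix(sim$traj)
  ics <- manual_ics(5:12)
  tab <- categorize_pairs(d, ics)
  cmp <- compare_categories(tab, contrasts = list(c("IC 1", "No IC")))
  expect_lt(cmp$tests$p[1], 0.01)
  expect_gt(cmp$tests$mean_a, cmp$tests$mean_b)
})
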