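paln_from_strings <- function(seqs, weights_threshold = 0.8) {
  aln <- new_msa(seqs)
  sequence_weights(
    preprocess_alignment(aln, "seq1", min_sid_to_ref = 0,
                         max_gap_frac_col = 1, max_gap_frac_seq = 1),
    weights_threshold)
}

test_that("positional frequencies match direct weighted counting", {
  paln <- paln_from_strings(c("AAAA", "AGAA", "AGCC", "AGC-"))
  f0 <- positional_frequencies(paln, lambda = 0)
  expect_equal(colSums(f0), rep(1, 4), ignore_attr = TRUE)
  w <- paln$weights / sum(paln$weights)
  # column 2: A for seq1, G for the rest
  expect_equal(f0["A", 2], unname(w[1]))
  expect_equal(f0["G", 2], unname(sum(w[2:4])))
  # column of all 'A' with lambda 0
  expect_equal(f0["A", 1], 1)
  expect_equal(sum(f0[-1, 1]), 0)
  # pseudocount blends toward uniform
  f <- positional_frequencies(paln, lambda = 0.03)
  expect_equal(f["A", 1], 0.97 + 0.03 / 21)
})

test_that("conservation is zero at background and matches the closed form", {
  q <- rep(0.05, 20)
  f_bg <- matrix(q, 20, 3)
  expect_equal(conservation(f_bg, q), rep(0, 3))
  f_cons <- matrix(0, 20, 1); f_cons[7, 1] <- 1
  expect_equal(conservation(f_cons, q), log(1 / 0.05), tolerance = 1e-12)
  # random column: term-by-term oracle
  set.seed(2)
  fr <- matrix(runif(20), 20, 1); fr <- fr / sum(fr)
  expected <- sum(fr * log(fr / q))
  expect_equal(unname(conservation(fr, q)), expected)
  expect_true(all(conservation(matrix(fr, 20, 5), q) >= 0))
})

test_that("coupling matrix is symmetric, near-zero for independent columns, and flags perfect covariation", {
  set.seed(4)
  # independent columns
  sim <- make_msa(n_seqs = 400, n_cols = 12, rho = 0, seed = 8)
  paln <- sequence_weights(
    preprocess_alignment(sim$aln, "seq1", min_sid_to_ref = 0), 0.8)
  m <- coupling_matrix(paln)
  expect_true(isSymmetric(unclass(m)))
  expect_true(all(is.finite(m)))

  # permutation-established sampling-noise bound for the independent case
  off <- unclass(m)[upper.tri(m)]
  null_off <- replicate(5, {
    mat <- unclass(paln$aln)
    for (j in seq_len(ncol(mat))) mat[, j] <- mat[sample(nrow(mat)), j]
    sh <- paln
    sh$aln <- structure(mat, class = c("msa", "matrix"))
    ms <- coupling_matrix(sh)
    max(unclass(ms)[upper.tri(ms)])
  })
  expect_lt(mean(off), max(null_off))

  # two perfectly covarying binary columns dominate the off-diagonal
  base <- unclass(make_msa(n_seqs = 200, n_cols = 8, rho = 0, seed = 9)$aln)
  half <- seq_len(100)
  base[, 4] <- "A"; base[, 7] <- "C"
  base[half, 4] <- "W"; base[half, 7] <- "Y"
  aln2 <- new_msa(apply(base, 1, paste, collapse = ""))
  paln2 <- sequence_weights(
    preprocess_alignment(aln2, "seq1", min_sid_to_ref = 0), 0.8)
  m2 <- unclass(coupling_matrix(paln2))
  diag(m2) <- 0
  expect_setequal(as.integer(which(m2 == max(m2), arr.ind = TRUE)[1, ]),
                  c(4L, 7L))
})

test_that("coupling matrix is invariant under sequence permutation", {
  sim <- make_msa(n_seqs = 150, n_cols = 15, groups = list(2:5), rho = 0.8,
                  seed = 13)
  paln <- sequence_weights(
    preprocess_alignment(sim$aln, "seq1", min_sid_to_ref = 0), 0.8)
  m1 <- coupling_matrix(paln)
  set.seed(1)
  perm <- sample(150)
  mat <- unclass(sim$aln)[perm, ]
  aln_p <- new_msa(apply(mat, 1, paste, collapse = ""), rownames(mat))
  paln_p <- sequence_weights(
    preprocess_alignment(aln_p, rownames(mat)[1], min_sid_to_ref = 0), 0.8)
  m2 <- coupling_matrix(paln_p)
  expect_equal(unclass(m1), unclass(m2), tolerance = 1e-10)
})

test_that("column shuffling sends off-diagonal coupling toward zero", {
  sim <- make_msa(n_seqs = 300, n_cols = 20, groups = list(1:6), rho = 0.9,
                  seed = 21)
  paln <- sequence_weights(
    preprocess_alignment(sim$aln, "seq1", min_sid_to_ref = 0), 0.8)
  m <- unclass(coupling_matrix(paln))
  set.seed(3)
  mat <- unclass(paln$aln)
  for (j in seq_len(ncol(mat))) mat[, j] <- mat[sample(nrow(mat)), j]
  sh <- paln
  sh$aln <- structure(mat, class = c("msa", "matrix"))
  ms <- unclass(coupling_matrix(sh))
  expect_lt(mean(ms[upper.tri(ms)]), mean(m[upper.tri(m)]))
})

test_that("decomposition recovers block support, k = 1 equals the leading eigenvector, eigenvalues are sorted", {
  # block-diagonal toy matrix with two disjoint blocks
  b <- matrix(0.2, 12, 12)
  b[1:5, 1:5] <- 0.9
  b[6:12, 6:12] <- 0.7
  diag(b) <- 1
  dimnames(b) <- list(1:12, 1:12)
  m <- structure(b, class = c("sca_matrix", "matrix"))
  dec <- sca_decompose(m, k = 2, seed = 2)
  expect_true(all(diff(dec$eigenvalues) <= 1e-12))
  top1 <- order(abs(dec$loadings[, 1]), decreasing = TRUE)[1:5]
  top2 <- order(abs(dec$loadings[, 2]), decreasing = TRUE)[1:5]
  in_block <- function(ix) all(ix %in% 1:5) || all(ix %in% 6:12)
  expect_true(in_block(top1))
  expect_true(in_block(top2))

  dec1 <- sca_decompose(m, k = 1, seed = 2)
  ev1 <- eigen(b, symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(as.numeric(dec1$loadings)), abs(ev1), tolerance = 1e-10)
  expect_error(sca_decompose(m, k = 0), "positive")
})

test_that("rank-k eigen reconstruction error never increases with k", {
  sim <- make_msa(n_seqs = 200, n_cols = 20, groups = list(1:4, 9:12),
                  rho = 0.9, seed = 17)
  paln <- sequence_weights(
    preprocess_alignment(sim$aln, "seq1", min_sid_to_ref = 0), 0.8)
  m <- unclass(coupling_matrix(paln))
  e <- eigen(m, symmetric = TRUE)
  errs <- vapply(1:5, function(k) {
    approx <- e$vectors[, 1:k, drop = FALSE] %*%
      diag(e$values[1:k], k) %*% t(e$vectors[, 1:k, drop = FALSE])
    norm(m - approx, "F")
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("select_k finds no components in i.i.d. columns and at least one for strong planting", {
  null_sim <- make_msa(n_seqs = 300, n_cols = 25, rho = 0, seed = 31)
  paln0 <- sequence_weights(
    preprocess_alignment(null_sim$aln, "seq1", min_sid_to_ref = 0), 0.8)
  m0 <- coupling_matrix(paln0)
  k0 <- sca_select_k(m0, paln0, n_randomizations = 5, seed = 2)$k
  expect_equal(k0, 0)

  sim <- make_msa(n_seqs = 300, n_cols = 25, groups = list(3:10), rho = 0.9,
                  seed = 32)
  paln <- sequence_weights(
    preprocess_alignment(sim$aln, "seq1", min_sid_to_ref = 0), 0.8)
  m <- coupling_matrix(paln)
  expect_gte(sca_select_k(m, paln, n_randomizations = 5, seed = 2)$k, 1)
})

test_that("position assignment respects the cutoff, disjointness, and the planted truth", {
  sim <- make_msa(n_seqs = 400, n_cols = 40, groups = list(5:12, 25:32),
                  rho = 0.9, seed = 41)
  paln <- sequence_weights(
    preprocess_alignment(sim$aln, "seq1", min_sid_to_ref = 0), 0.8)
  dec <- sca_decompose(coupling_matrix(paln), k = 2, seed = 4)

  ics <- assign_positions(dec, 0.95)
  # disjoint components
  expect_false(anyDuplicated(ics$assignments$ref_pos) > 0)
  expect_true(all(ics$assignments$ref_pos %in% dec$positions))
  # planted truth recovered
  expect_gte(min(recovery_jaccard(ics, sim$groups)), 0.75)
  # near-1 cutoff empties the assignment
  strict <- assign_positions(dec, 0.999999)
  expect_lte(nrow(strict$assignments), 2)
})
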