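# Statistical coupling analysis: weighted positional frequencies, relative
# entropy conservation, the conservation-weighted coupling matrix, its
# eigen/ICA decomposition, significance-based choice of the number of
# components, and per-position component assignment.

n_aa <- 20L

# 21-letter background: 20 amino acids scaled to (1 - gap share) plus the
# mean gap frequency of the alignment, the convention of sector analysis.
background21 <- function(freqs, background = AA_BACKGROUND) {
  gap_mean <- mean(freqs[21L, ])
  c(background * (1 - gap_mean), gap = gap_mean)
}

#' Weighted positional amino-acid frequencies
#'
#' Per-column frequencies over the 21-letter alphabet (20 residues + gap),
#' weighted by the redundancy-correcting sequence weights and regularised
#' with a pseudocount: `f = (1 - lambda) * f_weighted + lambda / 21`.
#'
#' @param paln A `processed_msa` with weights (see [sequence_weights()]).
#' @param lambda Pseudocount fraction in \[0,1\] (default 0.03).
#' @return 21 x n_cols matrix; rows named by [AA_ALPHABET21], columns sum to 1.
#' @export
positional_frequencies <- function(paln, lambda = 0.03) {
  if (!inherits(paln, "processed_msa")) abort("`paln` must be a processed_msa")
  if (is.null(paln$weights)) abort("call sequence_weights() first")
  assert_fraction(lambda, "lambda")
  X <- one_hot(paln$aln)
  w <- paln$weights / sum(paln$weights)
  f <- matrix(crossprod(X, w), nrow = 21L)
  f <- (1 - lambda) * f + lambda / 21
  rownames(f) <- AA_ALPHABET21
  colnames(f) <- paln$pos_map$ref_pos
  f
}

#' Positional conservation as relative entropy
#'
#' `D_i = sum_a f_i(a) * ln(f_i(a) / q(a))`, with `0 * ln 0 := 0`.
#'
#' @param freqs Frequency matrix (letters x positions), columns summing to 1,
#'   e.g. from [positional_frequencies()].
#' @param background Strictly positive background vector summing to 1, with
#'   as many entries as `freqs` has rows. Default extends [AA_BACKGROUND]
#'   with the alignment's mean gap frequency.
#' @return Numeric vector of per-position relative entropies (all `>= 0`).
#' @export
conservation <- function(freqs, background = NULL) {
  if (is.null(background)) background <- background21(freqs)
  if (length(background) != nrow(freqs)) {
    abort("`background` length must match the number of frequency rows")
  }
  if (any(background <= 0)) abort("`background` must be strictly positive")
  background <- background / sum(background)
  term <- freqs * log(sweep(freqs, 1L, background, "/"))
  term[freqs == 0] <- 0
  colSums(term)
}

# Conservation-gradient weight phi_i(a) = d D_i(a) / d f_i(a) for the
# binarised (residue vs not-residue) relative entropy.
phi_weights <- function(f, q) {
  f <- pmin(pmax(f, 1e-12), 1 - 1e-12)
  log(f * (1 - q) / ((1 - f) * q))
}

#' Conservation-weighted coupling matrix
#'
#' For each position pair (i, j) the co-variation tensor
#' `C_ij(a,b) = f_ij(a,b) - f_i(a) f_j(b)` is computed from weighted,
#' pseudocounted frequencies, each element reweighted by the conservation
#' gradients `phi_i(a) phi_j(b)`, and the matrix entry is the Frobenius norm
#' of the reweighted 20 x 20 block (gap co-variation is excluded from the
#' norm). The result is symmetric with nonnegative entries.
#'
#' @inheritParams positional_frequencies
#' @param background Background frequencies for the 20 amino acids
#'   (default [AA_BACKGROUND]).
#' @return An `sca_matrix`: positions x positions numeric matrix, dimnames =
#'   reference residue numbers, with the `processed_msa`'s position map
#'   attached as attribute `pos_map`.
#' @export
coupling_matrix <- function(paln, background = AA_BACKGROUND, lambda = 0.03) {
  if (!inherits(paln, "processed_msa")) abort("`paln` must be a processed_msa")
  if (is.null(paln$weights)) abort("call sequence_weights() first")
  p <- ncol(paln$aln)
  X <- one_hot(paln$aln)
  w <- paln$weights / sum(paln$weights)

  f1 <- as.numeric(crossprod(X, w))
  f1 <- (1 - lambda) * f1 + lambda / 21
  f21 <- matrix(f1, nrow = 21L)

  # degenerate columns: effectively all-gap after weighting
  degen <- colSums(f21[seq_len(n_aa), , drop = FALSE]) < 2 * lambda
  if (any(degen)) {
    warn(sprintf("excluding %d degenerate (all-gap) column(s): %s",
                 sum(degen), paste(which(degen), collapse = ", ")))
    keep <- !degen
    paln$aln <- structure(unclass(paln$aln)[, keep, drop = FALSE],
                          class = c("msa", "matrix"))
    paln$pos_map <- paln$pos_map[keep, ]
    return(coupling_matrix(paln, background, lambda))
  }

  Xw <- X * w
  f2 <- crossprod(Xw, X)
  f2 <- (1 - lambda) * f2 + lambda / (21^2)

  q21 <- background21(f21, background)
  phi <- phi_weights(f1, rep(q21, times = p))

  aa_idx <- as.vector(outer(seq_len(n_aa), (seq_len(p) - 1L) * 21L, "+"))
  C <- f2[aa_idx, aa_idx] - tcrossprod(f1[aa_idx])
  C <- C * tcrossprod(phi[aa_idx])

  E <- matrix(0, n_aa * p, p)   # block-sum indicator: rows (i,a) -> column i
  E[cbind(seq_len(n_aa * p), rep(seq_len(p), each = n_aa))] <- 1
  m <- sqrt(crossprod(E, C^2) %*% E)
  dimnames(m) <- list(paln$pos_map$ref_pos, paln$pos_map$ref_pos)
  structure(m, class = c("sca_matrix", "matrix"), pos_map = paln$pos_map)
}

# symmetric FastICA (logcosh contrast) returning an orthogonal unmixing
# matrix for pre-whitened k-dimensional data
fast_ica_rotation <- function(Z, max_iter = 500L, tol = 1e-8) {
  k <- ncol(Z); n <- nrow(Z)
  W <- matrix(rnorm(k * k), k, k)
  sym_orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_orth(W)
  for (it in seq_len(max_iter)) {
    WX <- Z %*% t(W)              # n x k sources
    G <- tanh(WX)
    gprime <- 1 - G^2
    W1 <- crossprod(G, Z) / n - diag(colMeans(gprime), k) %*% W
    W1 <- sym_orth(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) return(list(W = W, converged = TRUE, iter = it))
  }
  list(W = W, converged = FALSE, iter = max_iter)
}

#' Eigen decomposition and ICA rotation of the coupling matrix
#'
#' Extracts the top `k` eigenmodes of the coupling matrix and rotates them
#' with an independent component analysis (symmetric FastICA, logcosh
#' contrast) to maximise non-Gaussianity, yielding sparse independent
#' components whose large loadings identify coevolving position groups.
#' Each component's sign is fixed so its largest-magnitude loading is
#' positive; components are ordered by decreasing eigenvalue share.
#'
#' @param m An `sca_matrix` from [coupling_matrix()].
#' @param k Number of components (`1 <= k <=` matrix rank).
#' @param seed Integer seed for the ICA initialisation (recorded in the
#'   output; the result is deterministic given the seed).
#' @param max_restarts ICA restarts allowed on non-convergence before a hard
#'   error.
#' @return An `sca_decomposition`: list with `loadings` (positions x k, one
#'   column per IC), `eigenvalues` (all, non-increasing), `eigenvectors`
#'   (top k), `eigenvalue_share` (per IC), `k`, `seed`, `positions`.
#' @export
sca_decompose <- function(m, k, seed = 1L, max_restarts = 5L) {
  if (!is_count(k) || k < 1L) abort("`k` must be a positive integer")
  e <- eigen(m, symmetric = TRUE)
  rank <- sum(abs(e$values) > max(abs(e$values)) * 1e-12)
  if (k > rank) abort(sprintf("`k` (%d) exceeds matrix rank (%d)", k, rank))
  V <- e$vectors[, seq_len(k), drop = FALSE]
  lam <- e$values[seq_len(k)]

  if (k == 1L) {
    W <- matrix(1, 1, 1)
  } else {
    W <- NULL
    for (r in seq_len(max_restarts)) {
      res <- withr::with_seed(as.integer(seed) + r - 1L,
                              fast_ica_rotation(V))
      if (res$converged) { W <- res$W; break }
    }
    if (is.null(W)) abort("ICA failed to converge after restarts")
  }
  ics <- V %*% t(W)                       # positions x k

  # sign fix: largest-magnitude loading positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(ics[, j]))
    if (ics[i_max, j] < 0) ics[, j] <- -ics[, j]
  }
  # order by eigenvalue share of each component
  share <- as.numeric(W^2 %*% lam)
  ord <- order(share, decreasing = TRUE)
  ics <- ics[, ord, drop = FALSE]
  share <- share[ord]
  positions <- as.integer(rownames(m))
  dimnames(ics) <- list(positions, paste0("IC", seq_len(k)))
  structure(
    list(loadings = ics, eigenvalues = e$values,
         eigenvectors = V, eigenvalue_share = share,
         k = k, seed = seed, positions = positions),
    class = "sca_decomposition"
  )
}

#' @export
print.sca_decomposition <- function(x, ...) {
  cat(sprintf("<sca_decomposition> %d independent components over %d positions\n",
              x$k, length(x$positions)))
  cat("  top eigenvalues:",
      paste(sprintf("%.3f", head(x$eigenvalues, x$k)), collapse = ", "), "\n")
  invisible(x)
}

#' Choose the number of significant components
#'
#' Compares the eigenspectrum of the coupling matrix with the spectra of
#' coupling matrices computed from column-shuffled alignments (each column's
#' residues permuted independently across sequences, which destroys
#' inter-column coupling while preserving per-column conservation).
#' `k` is the number of real eigenvalues exceeding the maximum eigenvalue
#' seen across all randomisations.
#'
#' @param m An `sca_matrix` of the real alignment.
#' @param paln The `processed_msa` the matrix was computed from.
#' @param n_randomizations Number of shuffled replicates (default 10).
#' @param seed Integer seed for the shuffles.
#' @inheritParams coupling_matrix
#' @return List with `k`, `eigenvalues` (real), `null_max` (threshold), and
#'   `null_eigenvalues` (top eigenvalue per randomisation).
#' @export
sca_select_k <- function(m, paln, n_randomizations = 10L, seed = 1L,
                         background = AA_BACKGROUND, lambda = 0.03) {
  if (!is_count(n_randomizations) || n_randomizations < 1L) {
    abort("`n_randomizations` must be a positive integer")
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  null_top <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_randomizations), function(r) {
      sh <- paln
      mat <- unclass(paln$aln)
      for (j in seq_len(ncol(mat))) mat[, j] <- mat[sample(nrow(mat)), j]
      sh$aln <- structure(mat, class = c("msa", "matrix"))
      ms <- coupling_matrix(sh, background, lambda)
      eigen(ms, symmetric = TRUE, only.values = TRUE)$values[1L]
    }, numeric(1L))
  })
  thr <- max(null_top)
  list(k = sum(ev > thr), eigenvalues = ev, null_max = thr,
       null_eigenvalues = null_top)
}

# Maximum-likelihood t location-scale fit on unconstrained transformed
# parameters (mu, log s, log(df - 0.5)); returns NULL if optimisation fails.
fit_t_location_scale <- function(v) {
  nll <- function(par) {
    mu <- par[1]; s <- exp(par[2]); df <- 0.5 + exp(par[3])
    -sum(stats::dt((v - mu) / s, df, log = TRUE) - log(s))
  }
  init <- c(stats::median(v), log(stats::mad(v) + 1e-9), log(2))
  o <- tryCatch(
    stats::optim(init, nll, method = "Nelder-Mead",
                 control = list(maxit = 2000)),
    error = function(e) NULL)
  if (is.null(o) || o$convergence != 0 || !all(is.finite(o$par))) return(NULL)
  list(m = o$par[1], s = exp(o$par[2]), df = 0.5 + exp(o$par[3]))
}

#' Assign positions to independent components
#'
#' Fits a heavy-tailed location-scale (t) distribution to each component's
#' loadings and assigns to the component the positions whose loading exceeds
#' the fitted quantile at `cutoff_p` *and* is that position's largest
#' loading across components (ties broken toward the lower component index),
#' so components are disjoint.
#'
#' @param decomp An `sca_decomposition`.
#' @param cutoff_p Empirical cutoff fraction in (0,1); default 0.95.
#' @return An `ic_assignment`: list with `assignments` (tibble: `ref_pos`,
#'   `ic`, `loading`), `k`, `cutoff_p`, `positions` (all retained positions).
#' @export
assign_positions <- function(decomp, cutoff_p = 0.95) {
  assert_fraction(cutoff_p, "cutoff_p", closed_low = FALSE, closed_high = FALSE)
  L <- decomp$loadings
  k <- decomp$k
  cutoffs <- vapply(seq_len(k), function(j) {
    v <- L[, j]
    fit <- fit_t_location_scale(v)
    if (is.null(fit)) {
      warn(sprintf("t-distribution fit failed for IC%d; using empirical quantile", j))
      unname(quantile(v, cutoff_p, type = 7))
    } else {
      fit$m + fit$s * qt(cutoff_p, df = fit$df)
    }
  }, numeric(1L))

  best <- apply(L, 1L, which.max)     # lower index wins ties
  rows <- lapply(seq_len(k), function(j) {
    sel <- which(L[, j] > cutoffs[j] & best == j)
    tibble(ref_pos = decomp$positions[sel], ic = j, loading = unname(L[sel, j]))
  })
  assignments <- dplyr::arrange(dplyr::bind_rows(rows), .data$ic, .data$ref_pos)
  structure(
    list(assignments = assignments, k = k, cutoff_p = cutoff_p,
         cutoffs = cutoffs, positions = decomp$positions),
    class = "ic_assignment"
  )
}

#' @export
print.ic_assignment <- function(x, ...) {
  cat(sprintf("<ic_assignment> %d components, cutoff p = %.2f\n", x$k, x$cutoff_p))
  for (j in seq_len(x$k)) {
    pos <- x$assignments$ref_pos[x$assignments$ic == j]
    cat(sprintf("  IC%d (%d positions): %s\n", j, length(pos),
                paste(head(pos, 15L), collapse = ", ")))
  }
  invisible(x)
}

#' @rdname assign_positions
#' @param x An `ic_assignment`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ic_assignment <- function(x, ...) x$assignments
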