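# Synthetic-data generators with planted ground truth: alignments with
# coevolving column groups, Gaussian trajectories with block-structured
# correlated motion, and idealised toy structures. Every generator is
# deterministic given its seed.

#' Generate an alignment with planted coevolving column groups
#'
#' Background columns are drawn i.i.d. from per-column profiles in which a
#' dominant residue has probability `conservation` and the remaining 19
#' residues share the rest uniformly. Within each planted group a
#' per-sequence latent binary state selects one of two group-wide residue
#' patterns; each group column follows the latent state's pattern with
#' probability `rho` and otherwise falls back to its background profile.
#' Group columns therefore covary across sequences (strength governed by
#' `rho`, with `rho = 0` reducing to independent columns) while marginal
#' conservation stays near the stated level.
#'
#' @param n_seqs,n_cols Alignment dimensions.
#' @param groups List of disjoint integer column sets to plant.
#' @param rho Coupling strength in \[0,1\].
#' @param conservation Background dominant-residue probability (default 0.3).
#' @param seed Integer seed (bit-reproducible output).
#' @return List with `aln` (an `msa`), `groups` (the planted truth), and
#'   `patterns` (per group, the two residue patterns).
#' @export
make_msa <- function(n_seqs = 500L, n_cols = 100L,
                     groups = list(), rho = 0.9,
                     conservation = 0.3, seed = 1L) {
  assert_fraction(rho, "rho")
  assert_fraction(conservation, "conservation")
  if (length(groups) > 1L) {
    all_pos <- unlist(groups)
    if (anyDuplicated(all_pos)) abort("planted groups must be disjoint")
  }
  if (length(groups) && max(unlist(groups)) > n_cols) {
    abort("planted group column out of range")
  }
  aa <- AA_ALPHABET21[1:20]
  withr::with_seed(as.integer(seed), {
    dominant <- sample(aa, n_cols, replace = TRUE)
    mat <- matrix("", n_seqs, n_cols)
    for (j in seq_len(n_cols)) {
      prof <- rep((1 - conservation) / 19, 20)
      prof[match(dominant[j], aa)] <- conservation
      mat[, j] <- sample(aa, n_seqs, replace = TRUE, prob = prof)
    }
    patterns <- lapply(groups, function(g) {
      # two distinct residue patterns over the group's columns
      p1 <- dominant[g]
      p2 <- vapply(p1, function(a) sample(setdiff(aa, a), 1L), character(1L))
      list(p1 = unname(p1), p2 = unname(p2))
    })
    for (k in seq_along(groups)) {
      g <- groups[[k]]
      state <- sample(c(1L, 2L), n_seqs, replace = TRUE)
      for (ci in seq_along(g)) {
        j <- g[ci]
        obey <- runif(n_seqs) < rho
        pat <- ifelse(state == 1L, patterns[[k]]$p1[ci], patterns[[k]]$p2[ci])
        mat[obey, j] <- pat[obey]
      }
    }
    list(aln = new_msa(apply(mat, 1L, paste, collapse = "")),
         groups = groups, patterns = patterns)
  })
}

block_correlation <- function(n_residues, blocks, target_correlation) {
  C <- diag(n_residues)
  for (b in blocks) {
    C[b, b] <- target_correlation
    diag(C)[b] <- 1
  }
  C
}

#' Generate a trajectory with planted correlated-motion blocks
#'
#' Per frame, per-residue displacements are drawn from a zero-mean
#' multivariate Gaussian over residues with the given correlation matrix;
#' the same residue-level correlation is applied independently to each
#' Cartesian axis and scaled by `amplitude`, so the analytic DCC of the
#' ensemble equals the specified correlation matrix exactly. Displacements
#' are added to a reference structure (default an extended
#' alpha-carbon chain). Optionally each frame also receives a random
#' rigid-body motion, to exercise superposition.
#'
#' @param n_frames,n_residues Ensemble dimensions.
#' @param blocks List of residue index sets with correlated motion.
#' @param target_correlation Within-block correlation `c` in \[0,1\].
#' @param amplitude Per-residue fluctuation scale in Angstroms (scalar or
#'   length `n_residues`).
#' @param ref_xyz Optional reference coordinates (`n_residues` x 3 matrix).
#' @param rigid_motion Apply a random rotation + translation per frame.
#' @param seed Integer seed.
#' @return List with `traj` (a `traj_ensemble`, one CA atom per residue)
#'   and `analytic_dcc` (the planted correlation matrix as `dcc_matrix`).
#' @export
make_trajectory <- function(n_frames = 1000L, n_residues = 30L,
                            blocks = list(), target_correlation = 0.8,
                            amplitude = 1, ref_xyz = NULL,
                            rigid_motion = FALSE, seed = 1L) {
  C <- block_correlation(n_residues, blocks, target_correlation)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    abort(sprintf("correlation matrix is not positive semidefinite (smallest eigenvalue %.3g)",
                  min(ev)))
  }
  amplitude <- rep(amplitude, length.out = n_residues)
  if (any(amplitude <= 0)) abort("`amplitude` must be positive")
  if (is.null(ref_xyz)) {
    ref_xyz <- cbind(3.8 * (seq_len(n_residues) - 1), 0, 0)
  }
  R <- chol(C + diag(1e-10, n_residues))
  xyz <- withr::with_seed(as.integer(seed), {
    out <- matrix(0, n_frames, 3L * n_residues)
    for (ax in 1:3) {
      Z <- matrix(rnorm(n_frames * n_residues), n_frames) %*% R
      out[, (seq_len(n_residues) - 1L) * 3L + ax] <-
        sweep(Z, 2L, amplitude, "*") +
        matrix(ref_xyz[, ax], n_frames, n_residues, byrow = TRUE)
    }
    if (rigid_motion) {
      for (f in seq_len(n_frames)) {
        Q <- qr.Q(qr(matrix(rnorm(9), 3)))
        if (det(Q) < 0) Q[, 1] <- -Q[, 1]
        tr <- rnorm(3, sd = 10)
        fr <- matrix(out[f, ], ncol = 3L, byrow = TRUE) %*% t(Q)
        out[f, ] <- as.numeric(t(sweep(fr, 2L, tr, "+")))
      }
    }
    out
  })
  atoms <- tibble(eleno = seq_len(n_residues), elety = "CA", resid = "ALA",
                  chain = "A", resno = seq_len(n_residues))
  dimnames(C) <- list(seq_len(n_residues), seq_len(n_residues))
  list(traj = new_traj_ensemble(xyz, atoms),
       analytic_dcc = structure(C, class = c("dcc_matrix", "matrix")))
}

#' Build an idealised toy structure
#'
#' A single-frame ensemble of `n_residues` serine residues with backbone
#' (N, CA, C, O) plus CB and OG atoms, in an idealised `"helix"` (alpha
#' helix: 1.5 Angstrom rise, 100 degrees twist, 2.3 Angstrom CA radius) or
#' `"extended"` (3.8 Angstrom CA spacing) geometry. Enough atoms for
#' contact-mask and chi1 computations; round-trips through
#' [write_trajectory()] / [read_trajectory()].
#'
#' @param n_residues At least 3.
#' @param geometry `"helix"` or `"extended"`.
#' @return A `traj_ensemble` with one frame.
#' @export
make_toy_structure <- function(n_residues, geometry = c("helix", "extended")) {
  geometry <- match.arg(geometry)
  if (n_residues < 3L) abort("`n_residues` must be at least 3")
  ca <- if (geometry == "helix") {
    th <- (seq_len(n_residues) - 1) * 100 * pi / 180
    cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * (seq_len(n_residues) - 1))
  } else {
    cbind(3.8 * (seq_len(n_residues) - 1),
          0.4 * rep_len(c(-1, 1), n_residues), 0)
  }
  # local offsets from CA in a per-residue frame built from the chain
  # direction; magnitudes follow ideal covalent geometry closely enough for
  # distance and torsion tests
  rows <- list()
  xyz <- numeric(0)
  eleno <- 0L
  for (i in seq_len(n_residues)) {
    t_vec <- if (i < n_residues) ca[i + 1L, ] - ca[i, ] else ca[i, ] - ca[i - 1L, ]
    t_vec <- t_vec / sqrt(sum(t_vec^2))
    up <- c(0, 0, 1)
    if (abs(sum(up * t_vec)) > 0.9) up <- c(0, 1, 0)
    n_vec <- up - sum(up * t_vec) * t_vec
    n_vec <- n_vec / sqrt(sum(n_vec^2))
    b_vec <- c(t_vec[2] * n_vec[3] - t_vec[3] * n_vec[2],
               t_vec[3] * n_vec[1] - t_vec[1] * n_vec[3],
               t_vec[1] * n_vec[2] - t_vec[2] * n_vec[1])
    offs <- list(
      N  = -1.46 * t_vec + 0.30 * n_vec,
      CA = c(0, 0, 0),
      C  = 1.52 * t_vec + 0.30 * n_vec,
      O  = 1.52 * t_vec + 1.20 * n_vec + 0.40 * b_vec,
      CB = 1.10 * n_vec - 0.80 * b_vec,
      OG = 1.90 * n_vec - 1.40 * b_vec + 0.50 * t_vec
    )
    for (a in names(offs)) {
      eleno <- eleno + 1L
      rows[[eleno]] <- tibble(eleno = eleno, elety = a, resid = "SER",
                              chain = "A", resno = i)
      xyz <- c(xyz, ca[i, ] + offs[[a]])
    }
  }
  new_traj_ensemble(matrix(xyz, nrow = 1L), dplyr::bind_rows(rows))
}
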