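# Independent oracles used to cross-check package computations. These are
# deliberately naive implementations kept separate from the package code.

# Horn's quaternion-based optimal superposition: rotate+translate `mobile`
# (n x 3) onto `fixed` (n x 3), returning fitted coordinates and RMSD.
quaternion_superpose <- function(fixed, mobile) {
  cf <- colMeans(fixed); cm <- colMeans(mobile)
  A <- sweep(mobile, 2, cm); B <- sweep(fixed, 2, cf)
  S <- t(A) %*% B
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  fitted <- sweep(A %*% t(R), 2, cf, "+")
  list(fitted = fitted, rmsd = sqrt(mean(rowSums((fitted - fixed)^2))))
}

# Naive O(frames * n^2) DCC: explicit double loop over residues.
brute_dcc <- function(coords) {
  # coords: frames x residues x 3 array
  F <- dim(coords)[1]; n <- dim(coords)[2]
  mean_xyz <- apply(coords, c(2, 3), mean)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- 0; di <- 0; dj <- 0
      for (f in seq_len(F)) {
        a <- coords[f, i, ] - mean_xyz[i, ]
        b <- coords[f, j, ] - mean_xyz[j, ]
        num <- num + sum(a * b)
        di <- di + sum(a * a)
        dj <- dj + sum(b * b)
      }
      out[i, j] <- num / sqrt(di * dj)
    }
  }
  out
}

traj_coords_array <- function(traj, atom = "CA") {
  sel <- which(traj$atoms$elety == atom)
  F <- nrow(traj$xyz)
  arr <- array(0, c(F, length(sel), 3))
  for (k in seq_along(sel)) {
    arr[, k, ] <- traj$xyz[, (sel[k] - 1L) * 3L + 1:3, drop = FALSE]
  }
  arr
}

# Exhaustive two-sided Mann-Whitney p-value over all C(n+m, n) labelings.
brute_mwu <- function(x, y) {
  n <- length(x); m <- length(y)
  pool <- c(x, y)
  u_stat <- function(xi, yi) sum(outer(xi, yi, ">")) + 0.5 * sum(outer(xi, yi, "=="))
  U_obs <- u_stat(x, y)
  labelings <- combn(n + m, n)
  Us <- apply(labelings, 2, function(ix) u_stat(pool[ix], pool[-ix]))
  p_le <- mean(Us <= U_obs + 1e-12)
  p_ge <- mean(Us >= U_obs - 1e-12)
  list(U = U_obs, p = min(1, 2 * min(p_le, p_ge)))
}

# Torsion angle by an independent construction (Praxeolitic atan2 formula).
brute_torsion <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2; b1 <- p3 - p2; b2 <- p4 - p3
  b1n <- b1 / sqrt(sum(b1^2))
  v <- b0 - sum(b0 * b1n) * b1n
  w <- b2 - sum(b2 * b1n) * b1n
  x <- sum(v * w)
  y <- sum((c(b1n[2] * v[3] - b1n[3] * v[2],
              b1n[3] * v[1] - b1n[1] * v[3],
              b1n[1] * v[2] - b1n[2] * v[1])) * w)
  atan2(y, x) * 180 / pi   # IUPAC sign convention
}

# Mutual information between two alignment columns (natural log).
column_mi <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  mi <- 0
  for (i in seq_along(pa)) {
    for (j in seq_along(pb)) {
      if (tab[i, j] > 0) mi <- mi + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
    }
  }
  mi
}

# Jaccard index of the best-matching recovered component for each planted
# group, given an ic_assignment.
recovery_jaccard <- function(ics, groups) {
  vapply(groups, function(g) {
    best <- 0
    for (j in seq_len(max(ics$k, 1L))) {
      s <- ics$assignments$ref_pos[ics$assignments$ic == j]
      if (length(s) || length(g)) {
        best <- max(best, length(intersect(s, g)) / length(union(s, g)))
      }
    }
    best
  }, numeric(1))
}

# Small Stockholm fixture written on the fly.
write_toy_stockholm <- function(path, seqs = NULL) {
  if (is.null(seqs)) {
    seqs <- c(sp1 = "ACDEF", sp2 = "ACD-F", sp3 = "AC.EF")
  }
  lines <- c("# STOCKHOLM 1.0", "#=GF ID toy",
             sprintf("%-10s %s", names(seqs), unname(seqs)), "//")
  writeLines(lines, path)
  path
}
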