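# Structural observables: hinge-distance series, chi1 side-chain dihedrals,
# open/closed frame partitioning, and the residue contact mask used to
# exclude trivially correlated pairs.

#' Hinge-distance presets
#'
#' Residue-pair sets spanning the DHFR active-site cleft, measured at the
#' alpha carbon: `ecWT` (wild-type E. coli, pairs 22-53, 23-53, 24-53),
#' `ecMut` (N23PP/S148A mutant, 22-54, 23-54, 25-54), `human` (24-66,
#' 25-66, 27-66).
#'
#' @format Named list of 2-column matrices (`from`, `to` residue numbers).
#' @export
HINGE_PRESETS <- list(
  ecWT  = cbind(from = c(22L, 23L, 24L), to = c(53L, 53L, 53L)),
  ecMut = cbind(from = c(22L, 23L, 25L), to = c(54L, 54L, 54L)),
  human = cbind(from = c(24L, 25L, 27L), to = c(66L, 66L, 66L))
)

atom_xyz_by_resno <- function(traj, resno, atom) {
  at <- traj$atoms
  i <- which(at$resno == resno & at$elety == atom)
  if (length(i) == 0L) {
    abort(sprintf("atom '%s' missing for residue %d", atom, resno))
  }
  i[1L]
}

#' Per-frame hinge distance series
#'
#' For each frame, the arithmetic mean of the pairwise distances (default
#' alpha-carbon) over a set of residue pairs; summarised by the mean and
#' population variance over frames. Distances are internal coordinates, so
#' the series is invariant to rigid-body motion of each frame.
#'
#' @param traj A `traj_ensemble`.
#' @param pairs A 2-column matrix of residue-number pairs, or the name of a
#'   preset in [HINGE_PRESETS] (`"ecWT"`, `"ecMut"`, `"human"`).
#' @param atom Atom name measured (default `"CA"`).
#' @return A tibble (`frame`, `distance` in Angstroms) of class
#'   `hinge_series`, with attributes `mean`, `variance` (population), and
#'   `pairs`.
#' @export
hinge_series <- function(traj, pairs = "ecWT", atom = "CA") {
  if (is.character(pairs)) {
    if (!pairs %in% names(HINGE_PRESETS)) {
      abort(sprintf("unknown hinge preset '%s'", pairs))
    }
    pairs <- HINGE_PRESETS[[pairs]]
  }
  pairs <- as.matrix(pairs)
  d_per_pair <- vapply(seq_len(nrow(pairs)), function(r) {
    i <- atom_xyz_by_resno(traj, pairs[r, 1L], atom)
    j <- atom_xyz_by_resno(traj, pairs[r, 2L], atom)
    dx <- traj$xyz[, (i - 1L) * 3L + 1:3, drop = FALSE] -
      traj$xyz[, (j - 1L) * 3L + 1:3, drop = FALSE]
    sqrt(rowSums(dx^2))
  }, numeric(n_frames(traj)))
  if (!is.matrix(d_per_pair)) d_per_pair <- matrix(d_per_pair, nrow = 1L)
  d <- rowMeans(d_per_pair)
  out <- tibble(frame = seq_along(d), distance = d)
  structure(out, class = c("hinge_series", class(out)),
            mean = mean(d), variance = mean((d - mean(d))^2), pairs = pairs)
}

#' Chi1 side-chain dihedral series
#'
#' Signed torsion N-CA-CB-(gamma heavy atom) per frame, in degrees within
#' (-180, 180]. For serine the gamma atom is OG; the first present of
#' OG, OG1, SG, CG, CG1, CG2 is used.
#'
#' @param traj A `traj_ensemble`.
#' @param residue Residue number.
#' @return A tibble (`frame`, `angle` in degrees) of class `dihedral_series`
#'   with attribute `atoms` (the four atom names used).
#' @export
chi1_series <- function(traj, residue) {
  gamma_names <- c("OG", "OG1", "SG", "CG", "CG1", "CG2")
  present <- traj$atoms$elety[traj$atoms$resno == residue]
  gamma <- gamma_names[gamma_names %in% present][1L]
  if (is.na(gamma)) {
    abort(sprintf("residue %d has no gamma heavy atom (need one of %s)",
                  residue, paste(gamma_names, collapse = ", ")))
  }
  names4 <- c("N", "CA", "CB", gamma)
  idx <- vapply(names4, function(a) atom_xyz_by_resno(traj, residue, a),
                integer(1L))
  ang <- vapply(seq_len(n_frames(traj)), function(f) {
    coords <- as.numeric(vapply(idx, function(i)
      traj$xyz[f, (i - 1L) * 3L + 1:3], numeric(3L)))
    a <- bio3d::torsion.xyz(coords, atm.inc = 4)
    a[!is.na(a)][1L]
  }, numeric(1L))
  ang <- ((ang + 180) %% 360) - 180           # into (-180, 180]
  ang[ang == -180] <- 180
  out <- tibble(frame = seq_along(ang), angle = ang)
  structure(out, class = c("dihedral_series", class(out)), atoms = names4)
}

#' Select the most open or most closed frames
#'
#' Picks the top (`most_open`) or bottom (`most_closed`) `fraction` of
#' frames by a per-frame scalar metric (e.g. the hinge distance), with ties
#' broken deterministically by frame index.
#'
#' @param metric Numeric per-frame series, or a `hinge_series` tibble (its
#'   `distance` column is used).
#' @param mode `"most_open"` (largest values) or `"most_closed"` (smallest).
#' @param fraction Fraction of frames to keep, in (0, 1\]; default 0.25.
#' @return Sorted integer vector of frame indices.
#' @export
partition_frames <- function(metric, mode = c("most_open", "most_closed"),
                             fraction = 0.25) {
  mode <- match.arg(mode)
  if (inherits(metric, "hinge_series")) metric <- metric$distance
  assert_fraction(fraction, "fraction", closed_low = FALSE)
  n <- length(metric)
  n_keep <- max(1L, floor(fraction * n + 1e-9))
  key <- if (mode == "most_open") -metric else metric
  ord <- order(key, seq_len(n), method = "radix")
  sort(ord[seq_len(n_keep)])
}

#' Residue-pair exclusion mask from spatial and sequence proximity
#'
#' Marks residue pairs as excluded when their minimum heavy-atom distance in
#' the given structure frame is at most `distance_cutoff`, or when their
#' residue numbers differ by at most `seq_separation`. Used to drop
#' trivially correlated neighbours before comparing motion distributions
#' (the analysis convention is 5 Angstroms / 2 positions).
#'
#' @param traj A `traj_ensemble`; `frame` selects the structure used.
#' @param distance_cutoff Distance cutoff in Angstroms (default 5).
#' @param seq_separation Sequence-separation cutoff in positions (default 2).
#' @param frame Frame index (default 1; use the experimental starting
#'   structure).
#' @param method `"heavy"` (minimum over non-hydrogen atoms) or `"CA"`.
#' @return A `contact_mask`: symmetric logical matrix (TRUE = excluded) with
#'   residue numbers as dimnames; diagonal TRUE.
#' @export
contact_mask <- function(traj, distance_cutoff = 5, seq_separation = 2L,
                         frame = 1L, method = c("heavy", "CA")) {
  method <- match.arg(method)
  if (distance_cutoff <= 0) abort("`distance_cutoff` must be positive")
  if (seq_separation < 0) abort("`seq_separation` must be >= 0")
  at <- traj$atoms
  keep <- if (method == "CA") at$elety == "CA" else
    !grepl("^[0-9]*H", at$elety)
  idx <- which(keep)
  xyz <- matrix(traj$xyz[frame, bio3d::atom2xyz(idx)], ncol = 3L, byrow = TRUE)
  resno_atom <- at$resno[idx]
  resno <- sort(unique(at$resno))
  n <- length(resno)

  dmat <- as.matrix(stats::dist(xyz))
  grp <- factor(resno_atom, levels = resno)
  # minimum inter-residue heavy-atom distance via per-group reduction
  min_rr <- matrix(Inf, n, n)
  rows <- split(seq_along(idx), grp)
  for (i in seq_len(n)) {
    di <- dmat[rows[[i]], , drop = FALSE]
    min_over_i <- apply(di, 2L, min)
    min_rr[i, ] <- vapply(rows, function(r) min(min_over_i[r]), numeric(1L))
  }
  mask <- min_rr <= distance_cutoff
  sep <- abs(outer(resno, resno, "-")) <= seq_separation
  mask <- mask | sep
  mask <- mask | t(mask)
  diag(mask) <- TRUE
  dimnames(mask) <- list(resno, resno)
  structure(mask, class = c("contact_mask", "matrix"),
            distance_cutoff = distance_cutoff,
            seq_separation = seq_separation, method = method)
}
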