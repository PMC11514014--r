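# Trajectory container, multi-model PDB I/O, rigid-body superposition, and
# the dynamic cross-correlation (DCC) matrix.
#
# A `traj_ensemble` holds an `xyz` matrix (n_frames x 3*n_atoms, the bio3d
# layout: x1,y1,z1,x2,...) and an atom table shared by all frames.

new_traj_ensemble <- function(xyz, atoms) {
  stopifnot(is.matrix(xyz), ncol(xyz) == 3L * nrow(atoms))
  if (any(!is.finite(xyz))) abort("trajectory contains non-finite coordinates")
  structure(list(xyz = xyz, atoms = as_tibble(atoms)), class = "traj_ensemble")
}

#' @export
print.traj_ensemble <- function(x, ...) {
  cat(sprintf("<traj_ensemble> %d frames, %d atoms, %d residues\n",
              nrow(x$xyz), nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno)))))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `traj_ensemble`.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Read a (multi-model) PDB trajectory
#'
#' Models become frames; the atom table is taken from the first model and
#' every other model is validated against it (same atom count, names, and
#' residue numbers, in the same order).
#'
#' @param path PDB file; multi-model (MODEL/ENDMDL) or single structure.
#' @return A `traj_ensemble`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  validate_pdb_models(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  atoms <- tibble(
    eleno = pdb$atom$eleno, elety = pdb$atom$elety, resid = pdb$atom$resid,
    chain = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
    resno = pdb$atom$resno
  )
  new_traj_ensemble(xyz, atoms)
}

# text pre-scan: every MODEL must carry an identical atom record skeleton
validate_pdb_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  atom <- grepl("^(ATOM|HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) < 2L) return(invisible(TRUE))
  model_id <- findInterval(which(atom), model_starts)
  keys <- substr(lines[atom], 13, 27)  # atom name + resname + chain + resno
  keep <- model_id > 0L                # ignore records before the first MODEL
  by_model <- split(keys[keep], model_id[keep])
  ref <- by_model[[1L]]
  for (m in seq_along(by_model)[-1L]) {
    if (length(by_model[[m]]) != length(ref)) {
      abort(sprintf("model %d has %d atoms, expected %d", m,
                    length(by_model[[m]]), length(ref)))
    }
    if (!identical(by_model[[m]], ref)) {
      abort(sprintf("atom records of model %d do not match model 1", m))
    }
  }
  invisible(TRUE)
}

#' Write a trajectory as a (multi-model) PDB file
#'
#' @param traj A `traj_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  at <- traj$atoms
  con <- file(path, "w")
  on.exit(close(con))
  multi <- n_frames(traj) > 1L
  for (f in seq_len(n_frames(traj))) {
    if (multi) writeLines(sprintf("MODEL     %4d", f), con)
    xyz <- matrix(traj$xyz[f, ], ncol = 3L, byrow = TRUE)
    name4 <- ifelse(nchar(at$elety) < 4L, sprintf(" %-3s", at$elety),
                    substr(at$elety, 1, 4))
    writeLines(sprintf(
      "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
      at$eleno %% 100000L, name4, at$resid, at$chain, at$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# resolve a selection into atom indices
select_atoms <- function(traj, selection) {
  if (is.null(selection)) return(seq_len(nrow(traj$atoms)))
  if (is.logical(selection)) return(which(selection))
  if (is.numeric(selection)) return(as.integer(selection))
  if (is.character(selection)) return(which(traj$atoms$elety %in% selection))
  abort("`selection` must be NULL, logical, indices, or atom names")
}

#' Superpose trajectory frames onto a reference frame
#'
#' Least-squares optimal rigid-body (Kabsch) superposition of every frame
#' onto `reference_frame`, fitted on `selection` (default all alpha
#' carbons), with the per-frame RMSD over the selection computed after
#' fitting.
#'
#' @param traj A `traj_ensemble`.
#' @param reference_frame Frame index used as the fixed reference (default 1).
#' @param selection Atoms used for fitting and RMSD: `NULL` (all), a logical
#'   mask, atom indices, or atom names such as `"CA"`.
#' @return A `traj_ensemble` with aligned coordinates and an added `rmsd`
#'   element (tibble: `frame`, `rmsd`; Angstroms).
#' @export
superpose <- function(traj, reference_frame = 1L, selection = "CA") {
  idx <- select_atoms(traj, selection)
  if (length(idx) == 0L) abort("empty selection")
  xyz_idx <- bio3d::atom2xyz(idx)
  ref <- matrix(traj$xyz[reference_frame, xyz_idx], ncol = 3L, byrow = TRUE)
  ref_c <- sweep(ref, 2L, colMeans(ref))
  if (length(idx) < 3L || qr(ref_c)$rank < 2L) {
    abort("selection must contain at least 3 non-collinear atoms")
  }
  fitted <- bio3d::fit.xyz(fixed = traj$xyz[reference_frame, ],
                           mobile = traj$xyz,
                           fixed.inds = xyz_idx, mobile.inds = xyz_idx)
  if (!is.matrix(fitted)) fitted <- matrix(fitted, nrow = 1L)
  rmsd <- vapply(seq_len(nrow(fitted)), function(f) {
    d <- fitted[f, xyz_idx] - traj$xyz[reference_frame, xyz_idx]
    sqrt(mean(rowSums(matrix(d, ncol = 3L, byrow = TRUE)^2)))
  }, numeric(1L))
  out <- new_traj_ensemble(fitted, traj$atoms)
  out$rmsd <- tibble(frame = seq_along(rmsd), rmsd = rmsd)
  out
}

# one atom per residue, by atom-name preference
residue_atom_indices <- function(traj, atom = "CA") {
  at <- traj$atoms
  sel <- which(at$elety == atom)
  if (length(sel) == 0L) abort(sprintf("no '%s' atoms in trajectory", atom))
  key <- paste(at$chain[sel], at$resno[sel])
  if (anyDuplicated(key)) abort(sprintf("multiple '%s' atoms per residue", atom))
  sel
}

#' Dynamic cross-correlation matrix
#'
#' Normalised cross-correlation of positional fluctuations about the
#' time-mean structure: for residues i and j with displacement vectors
#' `dr = r - <r>`, `DCC(i,j) = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)`.
#' Computed on one atom per residue (default alpha carbons) of an aligned
#' trajectory; symmetric with unit diagonal, entries in \[-1, 1\].
#'
#' @param traj An aligned `traj_ensemble` (see [superpose()]) with at least
#'   two frames.
#' @param atom Atom name selecting one atom per residue (default `"CA"`).
#' @return A `dcc_matrix`: residues x residues numeric matrix with residue
#'   numbers as dimnames.
#' @export
dcc_matrix <- function(traj, atom = "CA") {
  if (n_frames(traj) < 2L) abort("DCC requires at least 2 frames")
  sel <- residue_atom_indices(traj, atom)
  resno <- traj$atoms$resno[sel]
  nf <- n_frames(traj); n <- length(sel)
  cov <- matrix(0, n, n)
  for (ax in 1:3) {
    D <- traj$xyz[, (sel - 1L) * 3L + ax, drop = FALSE]
    D <- sweep(D, 2L, colMeans(D))
    cov <- cov + crossprod(D) / nf
  }
  v <- diag(cov)
  if (any(v <= 0)) {
    abort(sprintf("zero positional fluctuation for residue(s): %s",
                  paste(resno[v <= 0], collapse = ", ")))
  }
  dcc <- cov / sqrt(tcrossprod(v))
  dcc <- (dcc + t(dcc)) / 2
  diag(dcc) <- 1
  dimnames(dcc) <- list(resno, resno)
  structure(dcc, class = c("dcc_matrix", "matrix"))
}

#' Tidy a DCC (or coupling) matrix into a long pair table
#'
#' @param x A `dcc_matrix` or `sca_matrix`.
#' @param ... Unused.
#' @return Tibble with `res_i`, `res_j` (i < j) and `value`.
#' @exportS3Method generics::tidy
tidy.dcc_matrix <- function(x, ...) {
  m <- unclass(x)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble(res_i = as.integer(rownames(m))[idx[, 1]],
         res_j = as.integer(colnames(m))[idx[, 2]],
         value = m[idx])
}

#' @rdname tidy.dcc_matrix
#' @exportS3Method generics::tidy
tidy.sca_matrix <- function(x, ...) {
  class(x) <- c("dcc_matrix", "matrix")
  tidy(x)
}
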