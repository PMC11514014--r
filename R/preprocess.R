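# Alignment preprocessing: reference truncation, gap filters, minimum
# identity to reference, position map, and redundancy-correcting sequence
# weights.

one_hot <- function(mat, letters = AA_ALPHABET21) {
  # n_seqs x (n_cols * n_letters) indicator matrix, column-major by alignment
  # column: block j holds the indicators for column j.
  n <- nrow(mat); p <- ncol(mat); L <- length(letters)
  idx <- match(mat, letters)            # column-major over mat
  out <- matrix(0, n, p * L)
  keep <- !is.na(idx)
  cols <- (rep(seq_len(p), each = n)[keep] - 1L) * L + idx[keep]
  out[cbind(rep(seq_len(n), p)[keep], cols)] <- 1
  out
}

# Fractional identity of every row of `mat` to every row of `mat2` (or all
# pairs within `mat`): matches / (columns where at least one is non-gap).
pairwise_identity <- function(mat) {
  X <- one_hot(mat, AA_ALPHABET21[1:20])
  G <- (unclass(mat) == "-") * 1
  matches <- X %*% t(X)
  both_gap <- G %*% t(G)
  denom <- ncol(mat) - both_gap
  id <- matches / pmax(denom, 1)
  id[denom == 0] <- 0
  id
}

identity_to_ref <- function(mat, ref_row) {
  ref <- unclass(mat)[ref_row, ]
  m <- sweep(unclass(mat), 2L, ref, "==")
  gap <- unclass(mat) == "-"
  ref_gap <- matrix(ref == "-", nrow(mat), ncol(mat), byrow = TRUE)
  matches <- rowSums(m & !gap)
  denom <- rowSums(!(gap & ref_gap))
  out <- matches / pmax(denom, 1)
  out[denom == 0] <- 0
  out
}

#' Preprocess an alignment for coupling analysis
#'
#' Applies, in this fixed order: (1) drop columns where the reference
#' sequence is gapped; (2) drop columns whose gap fraction exceeds
#' `max_gap_frac_col`; (3) drop sequences whose gap fraction exceeds
#' `max_gap_frac_seq`; (4) drop sequences with fractional identity to the
#' reference below `min_sid_to_ref`. A position map from retained alignment
#' columns to reference residue numbers is built from the reference's
#' non-gap positions.
#'
#' Fractional identity between two aligned sequences is defined as
#' matches / (columns where at least one sequence is non-gap).
#'
#' @param aln An `msa`, or a `processed_msa` to re-filter (the existing
#'   reference numbering is preserved, which makes the operation idempotent).
#' @param reference_id Identifier of the reference sequence (must be present).
#' @param min_sid_to_ref Minimum fractional identity to the reference
#'   (default 0.2; the human-biased rerun of the DHFR analysis used 0.4).
#' @param max_gap_frac_col,max_gap_frac_seq Maximum tolerated gap fraction
#'   per column / per sequence (defaults 0.2).
#' @param ref_start Residue number of the reference's first non-gap position
#'   (default 1).
#' @return A `processed_msa`: list with `aln` (filtered `msa`), `pos_map`
#'   (tibble: `column`, `ref_pos`), `reference_id`, `weights` (NULL until
#'   [sequence_weights()] is called), `n_effective`, `params`.
#' @export
preprocess_alignment <- function(aln, reference_id,
                                 min_sid_to_ref = 0.2,
                                 max_gap_frac_col = 0.2,
                                 max_gap_frac_seq = 0.2,
                                 ref_start = 1L) {
  assert_fraction(min_sid_to_ref, "min_sid_to_ref")
  assert_fraction(max_gap_frac_col, "max_gap_frac_col")
  assert_fraction(max_gap_frac_seq, "max_gap_frac_seq")
  if (inherits(aln, "processed_msa")) {
    ref_numbers <- aln$pos_map$ref_pos
    aln <- aln$aln
  } else {
    ref_numbers <- NULL
  }
  if (!inherits(aln, "msa")) abort("`aln` must be an msa or processed_msa")
  ref_row <- match(reference_id, rownames(aln))
  if (is.na(ref_row)) {
    abort(sprintf("reference sequence '%s' not found in alignment", reference_id))
  }
  mat <- unclass(aln)

  # (1) truncate to reference: drop columns gapped in the reference
  ref_nongap <- mat[ref_row, ] != "-"
  if (is.null(ref_numbers)) {
    ref_numbers <- cumsum(ref_nongap) + (ref_start - 1L)
  }
  mat <- mat[, ref_nongap, drop = FALSE]
  ref_numbers <- ref_numbers[ref_nongap]

  # (2) column gap filter
  col_gap <- colMeans(mat == "-")
  keep_col <- col_gap <= max_gap_frac_col
  mat <- mat[, keep_col, drop = FALSE]
  ref_numbers <- ref_numbers[keep_col]
  if (ncol(mat) == 0L) abort("all columns removed by gap filtering")

  # (3) sequence gap filter
  keep_seq <- rowMeans(mat == "-") <= max_gap_frac_seq
  if (!keep_seq[ref_row]) keep_seq[ref_row] <- TRUE  # never drop the reference
  mat <- mat[keep_seq, , drop = FALSE]
  ref_row <- match(reference_id, rownames(mat))

  # (4) minimum identity to reference
  sid <- identity_to_ref(structure(mat, class = c("msa", "matrix")), ref_row)
  keep_sid <- sid >= min_sid_to_ref
  keep_sid[ref_row] <- TRUE
  mat <- mat[keep_sid, , drop = FALSE]
  if (nrow(mat) == 0L) abort("all sequences removed by identity filtering")

  structure(
    list(
      aln = structure(mat, class = c("msa", "matrix")),
      pos_map = tibble(column = seq_len(ncol(mat)), ref_pos = ref_numbers),
      reference_id = reference_id,
      weights = NULL,
      n_effective = NA_real_,
      params = list(min_sid_to_ref = min_sid_to_ref,
                    max_gap_frac_col = max_gap_frac_col,
                    max_gap_frac_seq = max_gap_frac_seq,
                    ref_start = ref_start)
    ),
    class = "processed_msa"
  )
}

#' @export
print.processed_msa <- function(x, ...) {
  cat(sprintf("<processed_msa> %d sequences x %d positions (reference '%s')\n",
              nrow(x$aln), ncol(x$aln), x$reference_id))
  if (!is.null(x$weights)) {
    cat(sprintf("  effective sequences: %.2f (identity threshold %.2f)\n",
                x$n_effective, x$params$identity_threshold))
  }
  invisible(x)
}

#' Redundancy-correcting sequence weights
#'
#' The weight of sequence *s* is 1 / (number of sequences, including *s*
#' itself, whose fractional identity to *s* is at least
#' `identity_threshold`). The effective number of sequences is the sum of
#' the weights: a cluster of near-identical sequences counts as one.
#'
#' @param paln A `processed_msa`.
#' @param identity_threshold Identity threshold in (0,1); default 0.8.
#' @return The `processed_msa` with `weights` and `n_effective` filled in.
#' @export
sequence_weights <- function(paln, identity_threshold = 0.8) {
  if (!inherits(paln, "processed_msa")) abort("`paln` must be a processed_msa")
  assert_fraction(identity_threshold, "identity_threshold",
                  closed_low = FALSE, closed_high = FALSE)
  id <- pairwise_identity(paln$aln)
  n_similar <- rowSums(id >= identity_threshold)
  paln$weights <- setNames(1 / n_similar, rownames(paln$aln))
  paln$n_effective <- sum(paln$weights)
  paln$params$identity_threshold <- identity_threshold
  paln
}
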