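# Co-occurrence of the Met20-loop double-proline motif with residue
# identities at other alignment positions.

resolve_columns <- function(aln, positions, coords) {
  if (inherits(aln, "processed_msa")) {
    if (coords == "reference") {
      cols <- match(positions, aln$pos_map$ref_pos)
      if (anyNA(cols)) {
        abort(sprintf("reference position(s) not retained: %s",
                      paste(positions[is.na(cols)], collapse = ", ")))
      }
      return(list(mat = unclass(aln$aln), cols = cols))
    }
    return(list(mat = unclass(aln$aln), cols = positions))
  }
  if (!inherits(aln, "msa")) abort("`aln` must be an msa or processed_msa")
  if (coords == "reference") {
    abort("reference coordinates require a processed_msa with a position map")
  }
  list(mat = unclass(aln), cols = positions)
}

#' Flag sequences carrying a residue motif
#'
#' TRUE for each sequence holding the stated residues at the stated columns
#' (all of them); a gap at any motif column gives FALSE. The double-proline
#' Met20-loop motif is `motif_residues = "PP"` at the two columns aligned to
#' the insertion site.
#'
#' @param aln An `msa` or `processed_msa`.
#' @param positions Ordered column positions of the motif (length =
#'   `nchar(motif_residues)`).
#' @param motif_residues Residue string, e.g. `"PP"`.
#' @param coords `"column"` (raw column indices) or `"reference"` (reference
#'   residue numbers via the position map; `processed_msa` only).
#' @return Logical vector, one entry per sequence, named by sequence id.
#' @export
motif_flags <- function(aln, positions, motif_residues = "PP",
                        coords = c("column", "reference")) {
  coords <- match.arg(coords)
  res <- strsplit(toupper(motif_residues), "")[[1L]]
  if (length(positions) != length(res)) {
    abort("`positions` and `motif_residues` lengths differ")
  }
  rc <- resolve_columns(aln, positions, coords)
  if (any(rc$cols < 1L | rc$cols > ncol(rc$mat))) {
    abort("motif column out of range")
  }
  sub <- rc$mat[, rc$cols, drop = FALSE]
  flags <- rowSums(sweep(sub, 2L, res, "==")) == length(res)
  setNames(flags, rownames(rc$mat))
}

#' Motif x residue co-occurrence table
#'
#' Full 2x2 contingency of motif presence against residue identity at a
#' query column, over sequences. Gaps at the query column count as
#' mismatch. Counts are plain sequence counts by default; set
#' `weights` to the redundancy-correcting sequence weights for an
#' effective-sequence-weighted table.
#'
#' @inheritParams motif_flags
#' @param flags Logical per-sequence motif flags from [motif_flags()].
#' @param query_position Query column (interpretation set by `coords`).
#' @param query_residue Single residue character, e.g. `"G"`.
#' @param weights Optional numeric per-sequence weights (default unweighted).
#' @param fisher Also run Fisher's exact test on the 2x2 table (optional
#'   extra; not part of the replicated counting analysis).
#' @return A tibble with one row per cell: `motif` (TRUE/FALSE), `match`
#'   (TRUE/FALSE), `n`; attributes `totals` (named vector) and, if
#'   requested, `fisher_p`.
#' @export
motif_cooccurrence <- function(aln, flags, query_position, query_residue,
                               coords = c("column", "reference"),
                               weights = NULL, fisher = FALSE) {
  coords <- match.arg(coords)
  rc <- resolve_columns(aln, query_position, coords)
  if (length(flags) != nrow(rc$mat)) {
    abort("`flags` length must equal the number of sequences")
  }
  col <- rc$mat[, rc$cols[1L]]
  match_q <- col == toupper(query_residue)
  w <- weights %||% rep(1, length(flags))
  cells <- expand.grid(motif = c(TRUE, FALSE), match = c(TRUE, FALSE))
  n <- mapply(function(mo, ma) sum(w[flags == mo & match_q == ma]),
              cells$motif, cells$match)
  out <- tibble(motif = cells$motif, match = cells$match, n = n)
  attr(out, "totals") <- c(n_sequences = sum(w),
                           n_motif = sum(w[flags]),
                           n_match = sum(w[match_q]))
  if (fisher) {
    tab <- matrix(out$n, 2L, 2L)
    attr(out, "fisher_p") <- stats::fisher.test(round(tab))$p.value
  }
  class(out) <- c("cooccurrence_table", class(out))
  out
}
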