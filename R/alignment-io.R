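# Multiple sequence alignment container and I/O.
#
# An `msa` is a character matrix (sequences x columns) over the 21-letter
# alphabet (20 amino acids + gap), with sequence identifiers as rownames.

#' Construct an alignment object
#'
#' Builds an `msa` from raw sequence strings, normalising the alphabet:
#' letters are upper-cased, `.` becomes `-`, and any symbol outside the 20
#' standard amino acids (e.g. `X`, `B`, `Z`, `U`) becomes gap.
#'
#' @param seqs Character vector of aligned sequences (equal lengths).
#' @param seq_ids Character vector of identifiers, same length as `seqs`.
#' @return An `msa` object: a character matrix with class attribute, rownames
#'   = `seq_ids`.
#' @export
new_msa <- function(seqs, seq_ids = NULL) {
  if (length(seqs) == 0L) abort("alignment is empty")
  seq_ids <- seq_ids %||% paste0("seq", seq_along(seqs))
  if (length(seq_ids) != length(seqs)) {
    abort("`seq_ids` and `seqs` must have the same length")
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- seq_ids[which(lens != lens[1L])[1L]]
    abort(sprintf("ragged alignment: sequence '%s' has length %d, expected %d",
                  bad, nchar(seqs[seq_ids == bad][1L]), lens[1L]))
  }
  mat <- matrix(toupper(unlist(strsplit(seqs, "", fixed = TRUE))),
                nrow = length(seqs), byrow = TRUE)
  mat[mat == "."] <- "-"
  mat[!mat %in% AA_ALPHABET21] <- "-"
  rownames(mat) <- seq_ids
  structure(mat, class = c("msa", "matrix"))
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", nrow(x), ncol(x)))
  n_show <- min(5L, nrow(x))
  w <- min(60L, ncol(x))
  for (i in seq_len(n_show)) {
    cat(sprintf("  %-12s %s%s\n", substr(rownames(x)[i], 1, 12),
                paste(x[i, seq_len(w)], collapse = ""),
                if (ncol(x) > w) "..." else ""))
  }
  if (nrow(x) > n_show) cat(sprintf("  ... %d more\n", nrow(x) - n_show))
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Reads Stockholm 1.0 or aligned FASTA. Both `.` and `-` are accepted as
#' gaps; non-standard residue codes are normalised to gap (see [new_msa()]).
#'
#' @param path Path to the alignment file.
#' @param format `"stockholm"` or `"fasta"`. Default guesses from the first
#'   line (`# STOCKHOLM` header) and the file extension.
#' @return An `msa` object.
#' @export
read_alignment <- function(path, format = c("guess", "stockholm", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "guess") {
    first <- readLines(path, n = 1L)
    format <- if (length(first) && grepl("^#\\s*STOCKHOLM", first)) {
      "stockholm"
    } else "fasta"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    if (length(ss) == 0L) abort(sprintf("empty alignment file: %s", path))
    new_msa(as.character(ss), names(ss))
  } else {
    read_stockholm(path)
  }
}

# Minimal Stockholm 1.0 reader: concatenates multi-block sequence lines,
# skips '#' annotation and the terminating '//'.
read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) abort(sprintf("empty alignment file: %s", path))
  lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) &
                   nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("no sequences in Stockholm file: %s", path))
  parts <- regmatches(lines, regexpr("^\\S+", lines))
  seqs <- sub("^\\S+\\s+", "", lines)
  if (any(seqs == lines)) abort("malformed Stockholm record: missing sequence field")
  agg <- vapply(split(seqs, factor(parts, levels = unique(parts))),
                paste, character(1L), collapse = "")
  new_msa(unname(agg), names(agg))
}

#' Write an alignment as aligned FASTA
#'
#' @param aln An `msa` or `processed_msa`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  if (inherits(aln, "processed_msa")) aln <- aln$aln
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  ss <- Biostrings::BStringSet(setNames(seqs, rownames(aln)))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
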