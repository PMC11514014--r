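# Mapping DCC residue pairs onto independent-component categories and
# comparing |DCC| distributions across categories with two-sided
# Mann-Whitney U tests.

#' Piecewise-offset residue renumbering
#'
#' Builds a renumbering map from trajectory (DCC) residue numbers to the
#' alignment/reference numbering, as a list of `(after, offset)` rules:
#' every residue number strictly greater than `after` is shifted by
#' `offset`. The insertion convention of the N23PP mutant is
#' `renumbering(after = 23, offset = -1)`: trajectory residue 24 maps back
#' to reference position 23 while residues 1-23 are unchanged (the mutant's
#' numbering was shifted up by one after position 23).
#'
#' @param after Integer vector of breakpoints (strictly increasing).
#' @param offset Integer vector of offsets applied above each breakpoint
#'   (cumulative across rules).
#' @return A `renumbering` object.
#' @export
renumbering <- function(after = integer(), offset = integer()) {
  if (length(after) != length(offset)) {
    abort("`after` and `offset` must have the same length")
  }
  if (is.unsorted(after, strictly = TRUE)) {
    abort("`after` breakpoints must be strictly increasing")
  }
  structure(list(after = as.integer(after), offset = as.integer(offset)),
            class = "renumbering")
}

#' Apply or invert a renumbering
#'
#' @param renum A `renumbering`.
#' @param x Integer residue numbers.
#' @return Renumbered integers. `renumber()` checks that the map is
#'   strictly increasing (hence invertible) on the input.
#' @export
renumber <- function(renum, x) {
  if (!inherits(renum, "renumbering")) abort("`renum` must be a renumbering")
  ux <- sort(unique(as.integer(x)))
  if (is.unsorted(renumber_raw(renum, ux), strictly = TRUE)) {
    abort("renumbering is not strictly increasing on this input")
  }
  renumber_raw(renum, x)
}

renumber_raw <- function(renum, x) {
  y <- as.integer(x)
  for (r in seq_along(renum$after)) {
    y <- y + ifelse(as.integer(x) > renum$after[r], renum$offset[r], 0L)
  }
  y
}

#' @rdname renumber
#' @export
invert_renumbering <- function(renum) {
  # breakpoints move with the accumulated offset; offsets flip sign
  cum <- cumsum(renum$offset)
  renumbering(after = renum$after + cum, offset = -renum$offset)
}

#' Categorise DCC residue pairs by independent-component membership
#'
#' Builds the pair table underlying the sector-vs-dynamics comparison:
#' spatially or sequentially proximal pairs are dropped first (the
#' `contact_mask`), trajectory residue numbers are mapped to reference
#' numbering, and each retained pair (i < j) is labelled:
#'
#' * `"IC k"` — both residues assigned to component k;
#' * `"Not in same IC"` — every other retained pair;
#'
#' with two additional overlapping indicator columns: `any_ic` (both
#' residues in some component of `sector`, not necessarily the same) and
#' `no_ic` (neither residue in any component).
#'
#' @param dcc A `dcc_matrix`.
#' @param ics An `ic_assignment` (positions in reference numbering).
#' @param mask Optional `contact_mask` on the trajectory residue numbering.
#' @param renum Optional `renumbering` from trajectory to reference numbers.
#' @param sector Components considered for the `any_ic`/`no_ic` union
#'   (default all components of `ics`).
#' @param reference_positions Optional integer vector of valid reference
#'   positions; mapped residues outside it raise an error listing them.
#' @return A `pair_category_table` tibble: `res_i`, `res_j` (trajectory
#'   numbering), `ref_i`, `ref_j`, `dcc`, `abs_dcc`, `ic_i`, `ic_j`,
#'   `category`, `any_ic`, `no_ic`.
#' @export
categorize_pairs <- function(dcc, ics, mask = NULL, renum = NULL,
                             sector = NULL, reference_positions = NULL) {
  if (!inherits(dcc, "dcc_matrix")) abort("`dcc` must be a dcc_matrix")
  if (!inherits(ics, "ic_assignment")) abort("`ics` must be an ic_assignment")
  sector <- sector %||% seq_len(ics$k)
  pairs <- tidy(dcc)
  names(pairs)[names(pairs) == "value"] <- "dcc"

  if (!is.null(mask)) {
    mres_i <- match(as.character(pairs$res_i), rownames(mask))
    mres_j <- match(as.character(pairs$res_j), colnames(mask))
    if (anyNA(mres_i) || anyNA(mres_j)) {
      abort("contact mask does not cover all DCC residues")
    }
    pairs <- pairs[!mask[cbind(mres_i, mres_j)], , drop = FALSE]
  }

  ref_i <- if (is.null(renum)) pairs$res_i else renumber_raw(renum, pairs$res_i)
  ref_j <- if (is.null(renum)) pairs$res_j else renumber_raw(renum, pairs$res_j)
  if (!is.null(reference_positions)) {
    bad <- setdiff(unique(c(ref_i, ref_j)), reference_positions)
    if (length(bad)) {
      abort(sprintf("DCC residue(s) unmappable to reference numbering: %s",
                    paste(sort(bad), collapse = ", ")))
    }
  }

  amap <- ics$assignments
  amap <- amap[amap$ic %in% sector, , drop = FALSE]
  ic_i <- amap$ic[match(ref_i, amap$ref_pos)]
  ic_j <- amap$ic[match(ref_j, amap$ref_pos)]
  same <- !is.na(ic_i) & !is.na(ic_j) & ic_i == ic_j
  out <- tibble(
    res_i = pairs$res_i, res_j = pairs$res_j,
    ref_i = ref_i, ref_j = ref_j,
    dcc = pairs$dcc, abs_dcc = abs(pairs$dcc),
    ic_i = ic_i, ic_j = ic_j,
    category = ifelse(same, paste0("IC ", ic_i), "Not in same IC"),
    any_ic = !is.na(ic_i) & !is.na(ic_j),
    no_ic = is.na(ic_i) & is.na(ic_j)
  )
  class(out) <- c("pair_category_table", class(out))
  out
}

category_values <- function(table, category, use_abs = TRUE) {
  v <- if (use_abs) table$abs_dcc else table$dcc
  switch(category,
         "Any IC" = v[table$any_ic],
         "No IC" = v[table$no_ic],
         "Not in same IC" = v[table$category == "Not in same IC"],
         v[table$category == category])
}

#' Two-sided Mann-Whitney U test
#'
#' `U` counts pairs (x, y) with `x > y` plus half the ties. The two-sided
#' p-value is computed by exhaustive permutation enumeration when
#' `min(n, m) <= 8` and there are no ties across samples, and by the
#' normal approximation with tie and continuity corrections otherwise.
#'
#' @param x,y Nonempty numeric samples.
#' @return List with `U` (statistic for `x`), `p` (two-sided), and `method`.
#' @export
mwu_two_sided <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) abort("both samples must be nonempty")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0L

  if (!has_ties && min(n, m) <= 8L) {
    # exact: distribution of U over all C(n+m, n) labelings
    counts <- u_count_table(n, m)          # counts[u+1] = #labelings with U=u
    total <- sum(counts)
    p_le <- sum(counts[seq_len(floor(U) + 1L)]) / total
    p_ge <- sum(counts[(floor(U) + 1L):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(U = U, p = p, method = "exact"))
  }

  N <- n + m
  mu <- n * m / 2
  tie_tab <- table(r)
  tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
  sigma2 <- n * m / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(list(U = U, p = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  p <- max(min(1, 2 * pnorm(-abs(z))), .Machine$double.xmin)  # keep p in (0,1]
  list(U = U, p = p, method = "normal")
}

# Null distribution of U: counts[u+1] = number of labelings with U = u.
# The generating function is the Gaussian binomial coefficient
# [n+m choose n]_q = prod_{i=1..n} (1 - q^(m+i)) / (1 - q^i), built by
# polynomial multiplication and exact synthetic division.
u_count_table <- function(n, m) {
  a <- min(n, m); b <- max(n, m)    # distribution is symmetric in (n, m)
  P <- 1
  for (i in seq_len(a)) {
    # multiply by (1 - q^(b+i))
    P2 <- c(P, numeric(b + i))
    P2[(b + i + 1L):length(P2)] <- P2[(b + i + 1L):length(P2)] - P
    # divide by (1 - q^i): Q[u] = P2[u] + Q[u-i]
    Q <- P2
    if (length(Q) > i) {
      for (u in (i + 1L):length(Q)) Q[u] <- Q[u] + Q[u - i]
    }
    P <- Q[seq_len(i * b + 1L)]       # quotient polynomial has degree i*b
  }
  P
}

#' Compare |DCC| distributions across pair categories
#'
#' Summarises each category (count and mean |DCC|) and runs two-sided
#' Mann-Whitney U tests for the requested contrasts. The default contrasts
#' mirror the sector-dynamics analysis: each component against `"No IC"`,
#' each component against `"Not in same IC"`, and `"Any IC"` against
#' `"No IC"`. Raw p-values are reported (the analysis convention), with a
#' Benjamini-Hochberg column added for transparency. Significance stars:
#' `*` p <= 0.05, `**` p <= 0.01, `***` p <= 0.001, `****` p <= 0.0001.
#'
#' @param table A `pair_category_table` from [categorize_pairs()].
#' @param contrasts Optional list of 2-element character vectors naming
#'   category pairs; default as above.
#' @param use_abs Compare absolute DCC values (default TRUE; FALSE compares
#'   signed values).
#' @return An `ic_comparison`: list with `categories` (tibble: `category`,
#'   `n`, `mean`) and `tests` (tibble: `category_a`, `category_b`, `n_a`,
#'   `n_b`, `mean_a`, `mean_b`, `U`, `p`, `p_bh`, `stars`).
#' @export
compare_categories <- function(table, contrasts = NULL, use_abs = TRUE) {
  ic_cats <- sort(unique(table$category[table$category != "Not in same IC"]))
  all_cats <- c(ic_cats, "Any IC", "No IC", "Not in same IC")
  summ <- dplyr::bind_rows(lapply(all_cats, function(cc) {
    v <- category_values(table, cc, use_abs)
    tibble(category = cc, n = length(v),
           mean = if (length(v)) mean(v) else NA_real_)
  }))

  if (is.null(contrasts)) {
    contrasts <- c(
      lapply(ic_cats, function(cc) c(cc, "No IC")),
      lapply(ic_cats, function(cc) c(cc, "Not in same IC")),
      list(c("Any IC", "No IC"))
    )
  }
  rows <- lapply(contrasts, function(ct) {
    a <- category_values(table, ct[1L], use_abs)
    b <- category_values(table, ct[2L], use_abs)
    if (length(a) == 0L || length(b) == 0L) {
      warn(sprintf("skipping contrast '%s' vs '%s': empty category",
                   ct[1L], ct[2L]))
      return(NULL)
    }
    tst <- mwu_two_sided(a, b)
    tibble(category_a = ct[1L], category_b = ct[2L],
           n_a = length(a), n_b = length(b),
           mean_a = mean(a), mean_b = mean(b),
           U = tst$U, p = tst$p)
  })
  tests <- dplyr::bind_rows(rows)
  if (nrow(tests)) {
    tests$p_bh <- stats::p.adjust(tests$p, method = "BH")
    tests$stars <- significance_stars(tests$p)
  }
  structure(list(categories = summ, tests = tests, use_abs = use_abs),
            class = "ic_comparison")
}

significance_stars <- function(p) {
  cut_pts <- c(1e-4, 1e-3, 1e-2, 5e-2)
  vapply(p, function(pp) {
    strrep("*", sum(pp <= cut_pts))
  }, character(1L))
}

#' @export
print.ic_comparison <- function(x, ...) {
  cat("<ic_comparison>\n  category means",
      if (x$use_abs) "(|DCC|)" else "(signed DCC)", "\n")
  print(as.data.frame(x$categories), row.names = FALSE)
  cat("  tests:\n")
  print(as.data.frame(x$tests), row.names = FALSE)
  invisible(x)
}

#' Tidy / summarise an `ic_comparison`
#'
#' `tidy()` returns the per-contrast test table; `glance()` a one-row
#' summary (number of categories and contrasts, smallest raw p-value).
#'
#' @param x An `ic_comparison`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ic_comparison <- function(x, ...) x$tests

#' @rdname tidy.ic_comparison
#' @exportS3Method generics::glance
glance.ic_comparison <- function(x, ...) {
  tibble(n_categories = nrow(x$categories),
         n_contrasts = nrow(x$tests),
         n_pairs = x$categories$n[x$categories$category == "Not in same IC"] +
           sum(x$categories$n[grepl("^IC ", x$categories$category)]),
         min_p = if (nrow(x$tests)) min(x$tests$p) else NA_real_)
}
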