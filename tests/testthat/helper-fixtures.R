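# Shared fixture builders.

# an ic_assignment built directly from position sets
manual_ics <- function(...) {
  sets <- list(...)
  assignments <- dplyr::bind_rows(lapply(seq_along(sets), function(j) {
    tibble::tibble(ref_pos = as.integer(sets[[j]]), ic = j, loading = 1)
  }))
  structure(list(assignments = assignments, k = length(sets), cutoff_p = 0.95,
                 positions = sort(unique(assignments$ref_pos))),
            class = "ic_assignment")
}

# symmetric unit-diagonal matrix with given (or random) upper-triangle values
dcc_from_values <- function(n, fill = NULL) {
  m <- diag(n)
  if (is.null(fill)) {
    set.seed(99)
    v <- runif(n * (n - 1) / 2, -1, 1)
  } else {
    v <- fill
  }
  m[upper.tri(m)] <- v
  m <- m + t(m) - diag(diag(m))
  diag(m) <- 1
  dimnames(m) <- list(1:n, 1:n)
  structure(m, class = c("dcc_matrix", "matrix"))
}
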