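# ggplot2 views of the main result types.

#' Plot a DCC or coupling matrix as a heatmap
#'
#' @param object A `dcc_matrix` or `sca_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.dcc_matrix <- function(object, ...) {
  df <- tidy(object)
  df2 <- df
  names(df2)[1:2] <- c("res_j", "res_i")
  long <- dplyr::bind_rows(df, df2[, c("res_i", "res_j", "value")])
  ggplot2::ggplot(long, ggplot2::aes(.data$res_i, .data$res_j,
                                     fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-1, 1), name = "DCC") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "residue", y = "residue")
}

#' @rdname autoplot.dcc_matrix
#' @exportS3Method ggplot2::autoplot
autoplot.sca_matrix <- function(object, ...) {
  df <- tidy(object)
  df2 <- df
  names(df2)[1:2] <- c("res_j", "res_i")
  long <- dplyr::bind_rows(df, df2[, c("res_i", "res_j", "value")])
  ggplot2::ggplot(long, ggplot2::aes(.data$res_i, .data$res_j,
                                     fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "coupling") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "position", y = "position")
}

#' Box plot of |DCC| by pair category
#'
#' @param object A `pair_category_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pair_category_table <- function(object, ...) {
  cats <- sort(unique(object$category[object$category != "Not in same IC"]))
  long <- dplyr::bind_rows(lapply(c(cats, "Any IC", "No IC", "Not in same IC"),
    function(cc) {
      tibble(category = cc, abs_dcc = category_values(object, cc, TRUE))
    }))
  ggplot2::ggplot(long, ggplot2::aes(.data$category, .data$abs_dcc)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "|DCC|")
}

#' Per-frame series plots
#'
#' @param object A `hinge_series` or `dihedral_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.hinge_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$frame, .data$distance)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "frame", y = "mean hinge distance (Å)")
}

#' @rdname autoplot.hinge_series
#' @exportS3Method ggplot2::autoplot
autoplot.dihedral_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$angle)) +
    ggplot2::geom_histogram(binwidth = 10, boundary = -180) +
    ggplot2::scale_x_continuous(limits = c(-180, 180)) +
    ggplot2::labs(x = "chi1 (degrees)", y = "frames")
}
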