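# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a signature result
#'
#' `type = "spectrum"`: histogram of the empirical eigenvalues with the null
#' bulk density overlaid and the upper edge marked — eigenvalues beyond the
#' edge carry the structure. `type = "matrix"`: the filtered correlation
#' matrix as a heatmap with units ordered by module, showing the sign-block
#' structure.
#'
#' @param object A `funsig_result`.
#' @param type `"spectrum"` or `"matrix"`.
#' @param bulk_only For the spectrum, drop eigenvalues above 3 times the
#'   upper edge so the bulk is visible next to a large global mode.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.funsig_result <- function(object, type = c("spectrum", "matrix"),
                                   bulk_only = TRUE, ...) {
  type <- match.arg(type)
  if (type == "spectrum") {
    lam <- object$eigen$values
    lim <- if (bulk_only) 3 * object$bounds$lambda_plus else Inf
    df <- tibble::tibble(eigenvalue = lam[lam <= lim])
    grid <- seq(max(object$bounds$lambda_minus, 1e-9), object$bounds$lambda_plus,
                length.out = 200)
    dens <- tibble::tibble(eigenvalue = grid,
                           density = null_density(object$bounds, grid))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$eigenvalue)) +
      ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                              bins = 40, fill = "grey70", colour = "grey40") +
      ggplot2::geom_line(data = dens, ggplot2::aes(y = .data$density),
                         colour = "firebrick", linewidth = 0.8) +
      ggplot2::geom_vline(xintercept = object$bounds$lambda_plus,
                          linetype = "dashed", colour = "firebrick") +
      ggplot2::labs(x = "eigenvalue", y = "density",
                    title = "Correlation spectrum vs null bulk")
  } else {
    ord <- order(object$partition$labels)
    M <- object$filtered$C_filtered[ord, ord]
    df <- tidyr::expand_grid(row = seq_len(nrow(M)), col = seq_len(ncol(M)))
    df$value <- as.vector(M)[(df$col - 1) * nrow(M) + df$row]
    ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                     fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                    high = "firebrick") +
      ggplot2::scale_y_reverse() +
      ggplot2::labs(x = NULL, y = NULL, fill = "residual\ncorrelation",
                    title = "Filtered matrix, units ordered by module")
  }
}

#' Plot a threshold sweep (S and M curves)
#'
#' @param object A `threshold_sweep`.
#' @param ... Unused.
#' @return A ggplot object with the largest-component fraction `S` and
#'   community fraction `M` against the threshold.
#' @export
autoplot.threshold_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(dplyr::select(tibble::as_tibble(object),
                                          "threshold", "S", "M"),
                            c("S", "M"), names_to = "curve")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$value,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(S = "steelblue", M = "firebrick")) +
    ggplot2::labs(y = "fraction", title = "Threshold sweep: no optimal threshold")
}

#' Plot a co-classification matrix
#'
#' @param object A `coclassification`.
#' @param order_by Optional `funsig_partition` used to order units.
#' @param ... Unused.
#' @return A ggplot heatmap of co-assignment frequencies.
#' @export
autoplot.coclassification <- function(object, order_by = NULL, ...) {
  ord <- if (!is.null(order_by)) order(order_by$labels) else seq_len(nrow(object$F))
  M <- object$F[ord, ord]
  df <- tidyr::expand_grid(row = seq_len(nrow(M)), col = seq_len(ncol(M)))
  df$value <- as.vector(M)[(df$col - 1) * nrow(M) + df$row]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = NULL, fill = "co-assignment",
                  title = sprintf("Co-classification over %d runs", object$n_runs))
}
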