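# ggplot2 views of the main result types

#' Plot a synthetic field
#'
#' Shows the two channels side by side, with the conventional colours
#' (green FITC, red counterstain).
#'
#' @param object a `labeled_field`.
#' @param downsample keep every n-th pixel for display.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot labeled_field
#' @export
autoplot.labeled_field <- function(object, downsample = 2, ...) {
  grab <- function(m, ch) {
    ri <- seq(1, nrow(m), by = downsample)
    ci <- seq(1, ncol(m), by = downsample)
    expand.grid(row = ri, col = ci) |>
      tibble::as_tibble() |>
      dplyr::mutate(value = m[cbind(.data$row, .data$col)], channel = ch)
  }
  df <- dplyr::bind_rows(grab(object$fitc, "FITC"),
                         grab(object$counterstain, "counterstain"))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_void()
}

#' Plot per-pattern recognition rates
#'
#' Bar chart of a [pattern_table()] result.
#'
#' @param table tibble from [pattern_table()].
#' @return a ggplot.
#' @export
plot_pattern_rates <- function(table) {
  df <- dplyr::filter(table, .data$pattern != "total")
  ggplot2::ggplot(df, ggplot2::aes(stats::reorder(.data$pattern, .data$rate),
                                   .data$rate)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$rate)),
                       hjust = -0.1, size = 3) +
    ggplot2::coord_flip(ylim = c(0, 105)) +
    ggplot2::labs(x = NULL, y = "main pattern recognized (%)") +
    ggplot2::theme_minimal()
}

#' Plot a dilution series' intensity decay
#'
#' Normalized intensity per well against dilution on a log axis, with the
#' positive/negative cutoff drawn in.
#'
#' @param wells list of `well_result`s.
#' @param cutoff cutoff to draw.
#' @return a ggplot.
#' @export
plot_dilution_series <- function(wells, cutoff = 0.15) {
  df <- purrr::map_dfr(wells, function(w)
    tibble::tibble(dilution = w$dilution, intensity = w$intensity,
                   positive = w$positive))
  ggplot2::ggplot(df, ggplot2::aes(.data$dilution, .data$intensity)) +
    ggplot2::geom_hline(yintercept = cutoff, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line(colour = "seagreen") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$positive), size = 3) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "reciprocal dilution", y = "normalized intensity",
                  colour = "positive") +
    ggplot2::theme_minimal()
}
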