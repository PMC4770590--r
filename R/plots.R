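# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a smooth foraging-success response curve
#'
#' Scatter of the data with the fitted penalized-spline smooth and a marker
#' at its argmax (the estimated thermal optimum when x is SST).
#'
#' @param object A `gam_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.gam_fit <- function(object, ...) {
  grid <- tibble(
    x = seq(object$xl, object$xr, length.out = 300)
  )
  grid$y <- predict(object, grid$x)
  ggplot2::ggplot(tibble(x = object$x, y = object$y), ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid, colour = "firebrick", linewidth = 1) +
    ggplot2::geom_vline(xintercept = object$argmax, linetype = 2) +
    ggplot2::labs(
      x = "Predictor", y = "Response",
      subtitle = sprintf(
        "P-spline smooth (edf %.1f, R² %.2f); argmax %.2f",
        object$edf, object$r_squared, object$argmax
      )
    ) +
    ggplot2::theme_minimal()
}

#' Map per-cell values on the analysis grid
#'
#' @param cells Tibble with `ix, iy` and the fill column.
#' @param fill Unquoted column to map to fill (e.g. `anomaly_c`, `count`).
#' @param grid A [grid_spec()] (for axis scales in km).
#' @return A ggplot.
#' @export
plot_cells <- function(cells, fill, grid = NULL) {
  fill <- rlang::enquo(fill)
  p <- ggplot2::ggplot(cells, ggplot2::aes(.data$ix, .data$iy, fill = !!fill)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "cell east", y = "cell north") +
    ggplot2::theme_minimal()
  if (is.numeric(rlang::eval_tidy(fill, cells))) {
    p <- p + ggplot2::scale_fill_viridis_c()
  }
  p
}

#' Plot a trip-decile SST/capture profile
#'
#' @param profile Tibble from [decile_profile()].
#' @return A ggplot with SST and mean captures per trip-fraction decile.
#' @export
plot_decile_profile <- function(profile) {
  long <- tidyr::pivot_longer(profile, -"decile",
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$decile, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::scale_x_continuous(breaks = 1:10) +
    ggplot2::labs(x = "Trip fraction decile", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a daily series with its rolling mean
#'
#' @param smoothed Tibble from [rolling_mean()].
#' @return A ggplot.
#' @export
plot_series <- function(smoothed) {
  ggplot2::ggplot(smoothed, ggplot2::aes(.data$date, .data$value)) +
    ggplot2::geom_point(alpha = 0.3, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smoothed),
      colour = "steelblue", linewidth = 0.8, na.rm = TRUE
    ) +
    ggplot2::labs(x = NULL, y = "value") +
    ggplot2::theme_minimal()
}
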