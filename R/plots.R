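wetland_palette <- function() {
  c(open_water = "#2166ac", mudflat = "#8c7a5b", mangrove = "#1a7837",
    mixed = "#7fbc41", saltmarsh = "#d9b44a", casuarina = "#5e3c99",
    upland = "#b8b8b8")
}

#' Plot methods
#'
#' `autoplot()` methods for the package's result types: a categorical
#' raster map for vegetation grids, a hillshade-free elevation map for
#' DEMs, class-area trajectories for runs and comparisons, and a signed
#' heatmap for sensitivity tables.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vegetation_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df[!is.na(df$value), ],
                  ggplot2::aes(.data$x, .data$y, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = wetland_palette(), drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)", fill = NULL)
}

#' @rdname autoplot.vegetation_grid
#' @export
autoplot.elevation_grid <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df[!is.na(df$value), ],
                  ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "cividis") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)",
                  fill = "elevation (m)")
}

#' @rdname autoplot.vegetation_grid
#' @export
autoplot.wetland_run <- function(object, ...) {
  ggplot2::ggplot(object$areas,
                  ggplot2::aes(.data$year, .data$area_ha,
                               colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = wetland_palette(), drop = FALSE) +
    ggplot2::labs(x = "year", y = "area (ha)", colour = NULL)
}

#' @rdname autoplot.vegetation_grid
#' @export
autoplot.model_comparison <- function(object, ...) {
  ggplot2::ggplot(object$areas,
                  ggplot2::aes(.data$year, .data$area_ha,
                               colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~engine) +
    ggplot2::scale_colour_manual(values = wetland_palette(), drop = FALSE) +
    ggplot2::labs(x = "year", y = "area (ha)", colour = NULL)
}

#' @rdname autoplot.vegetation_grid
#' @export
autoplot.sensitivity_table <- function(object, ...) {
  df <- object[object$direction == "+", ]
  ggplot2::ggplot(df, ggplot2::aes(.data$parameter, .data$class,
                                   fill = .data$pct_change)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = NULL, y = NULL, fill = "% change",
                  subtitle = sprintf("+%g%% one-at-a-time perturbation",
                                     100 * attr(object, "perturbation")))
}
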