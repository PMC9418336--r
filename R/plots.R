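#' Plot a class map
#'
#' @param map a `class_map`.
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_class_map <- function(map, ...) {
  stopifnot(inherits(map, "class_map"))
  df <- as_tibble(field_grid(map$values + 0, map$pixel_size, map$origin))
  df$class <- factor(class_catalog()$class[df$value],
                     levels = class_catalog()$class)
  pal <- c(active_cropland = "#e6b82a", short_fallow = "#c98f52",
           herbaceous = "#a8d08d", open_woodland = "#5e9e5a",
           closed_woodland = "#1d5e33", unvegetated = "#b8b2a7",
           water = "#3a6ea5")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a continuous grid (noise map, margin map, feature layer)
#'
#' @param grid a `field_grid`.
#' @param trans transformation for the fill scale (e.g. `"sqrt"`).
#' @return a ggplot.
#' @export
plot_grid_layer <- function(grid, trans = "identity") {
  stopifnot(inherits(grid, "field_grid"))
  df <- as_tibble(grid)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans, na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)", fill = grid$name) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.field_grid <- function(object, ...) plot_grid_layer(object, ...)

#' @export
autoplot.class_map <- function(object, ...) plot_class_map(object, ...)

#' Accuracy plot of an error-matrix estimate
#'
#' Point-range chart of user's and producer's accuracy per class with 95%
#' confidence intervals (where counts are available).
#'
#' @param object an `error_matrix_estimate`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.error_matrix_estimate <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("ua", "pa"), names_to = "measure",
                        values_to = "accuracy") |>
    dplyr::mutate(ci = ifelse(.data$measure == "ua", .data$ua_ci, .data$pa_ci),
                  measure = dplyr::recode(.data$measure, ua = "user's",
                                          pa = "producer's"))
  ggplot2::ggplot(df, ggplot2::aes(.data$class, .data$accuracy,
                                   colour = .data$measure)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = pmax(0, .data$accuracy - .data$ci),
                   ymax = pmin(1, .data$accuracy + .data$ci)),
      position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "accuracy", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot the fallow-share curve
#'
#' @param curve tibble from [fallow_share_curve()].
#' @return a ggplot.
#' @export
plot_fallow_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$bin_mid, .data$median)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "grey80") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "total cropland share per grid cell",
                  y = "fallow fraction of cropland (median, IQR)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
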