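#' Plot a projected cohort coloured by a variable
#'
#' Scatter of the unit-square projection, coloured by an outcome or
#' predictor column (e.g. `survived_12m`, `alsfrs_12m`).
#'
#' @param projected Tibble with `x`, `y` and the colouring column.
#' @param colour Column to colour by (tidy-eval); default `survived_12m`.
#' @return A ggplot object.
#' @export
plot_projection <- function(projected, colour = survived_12m) {
  ggplot2::ggplot(projected,
                  ggplot2::aes(.data$x, .data$y,
                               colour = {{ colour }})) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "projection x", y = "projection y") +
    ggplot2::theme_minimal()
}

utils::globalVariables("survived_12m")

#' Autoplot a square-cell survival map
#'
#' Heatmap of per-cell 1-year survival rates; empty cells are blank.
#'
#' @param object An `als_cell_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot als_cell_map
#' @export
autoplot.als_cell_map <- function(object, ...) {
  s <- attr(object, "cell_size")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = (.data$cell_x + 0.5) * s,
                               y = (.data$cell_y + 0.5) * s,
                               fill = .data$rate)) +
    ggplot2::geom_tile(width = s, height = s, colour = "grey80") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "white",
                                  name = "survival rate") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "projection x", y = "projection y") +
    ggplot2::theme_minimal()
}

#' Autoplot a zone model
#'
#' Draws the zone cut lines over the unit square with each zone shaded by
#' its survival rate and annotated with rate and Wald interval.
#'
#' @param object An `als_zones`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot als_zones
#' @export
autoplot.als_zones <- function(object, ...) {
  edges <- c(0, object$cuts, 1)
  zones <- tidy(object)
  zones$lo_edge <- edges[-length(edges)]
  zones$hi_edge <- edges[-1]
  zones$mid <- (zones$lo_edge + zones$hi_edge) / 2
  horizontal <- object$axis == "y"
  p <- ggplot2::ggplot(zones) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = if (horizontal) 0 else .data$lo_edge,
      xmax = if (horizontal) 1 else .data$hi_edge,
      ymin = if (horizontal) .data$lo_edge else 0,
      ymax = if (horizontal) .data$hi_edge else 1,
      fill = .data$rate), alpha = 0.8) +
    ggplot2::geom_text(ggplot2::aes(
      x = if (horizontal) 0.5 else .data$mid,
      y = if (horizontal) .data$mid else 0.5,
      label = sprintf("%s: %.0f%% ± %.0f%%", .data$label,
                      100 * .data$rate, 100 * .data$width / 2))) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "survival rate") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "projection x", y = "projection y") +
    ggplot2::theme_minimal()
  p
}
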