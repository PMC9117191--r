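# ggplot2 display methods for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a zone frequency table
#'
#' @param object A `freq_table`.
#' @param ... Unused.
#' @return A ggplot: presence proportion by zone, faceted by year.
#' @method autoplot freq_table
#' @export
autoplot.freq_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$zone, y = .data$proportion,
                                       fill = .data$zone)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~year) +
    ggplot2::scale_y_continuous(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = NULL, y = "plots with mole mounds",
                  title = "Mole presence by survey zone") +
    ggplot2::theme_minimal()
}

#' Plot a density grid
#'
#' @param object A `density_grid`.
#' @param ... Unused.
#' @return A ggplot raster of the density surface.
#' @method autoplot density_grid
#' @export
autoplot.density_grid <- function(object, ...) {
  df <- grid_to_df(object$values, object$origin, object$cell_size)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "density") +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Plot a grid region
#'
#' @param object A `grid_region`.
#' @param ... Unused.
#' @return A ggplot raster of the region mask.
#' @method autoplot grid_region
#' @export
autoplot.grid_region <- function(object, ...) {
  df <- grid_to_df(object$mask, object$origin, object$cell_size)
  ggplot2::ggplot(df[df$value, ], ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(fill = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)",
                  title = sprintf("Region, %.2f ha", object$area_ha)) +
    ggplot2::theme_minimal()
}

#' Plot an orthoimage with its truth boxes
#'
#' @param object An `ortho_image`.
#' @param boxes Optional extra boxes (e.g. predictions) drawn in red.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ortho_image
#' @export
autoplot.ortho_image <- function(object, boxes = NULL, ...) {
  px <- object$pixels
  df <- tibble::tibble(
    col = rep(seq_len(ncol(px)), each = nrow(px)) - 0.5,
    row = rep(seq_len(nrow(px)), ncol(px)) - 0.5,
    value = as.vector(px))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "px", y = "px") +
    ggplot2::theme_minimal()
  if (nrow(object$truth) > 0) {
    p <- p + ggplot2::geom_rect(
      data = object$truth, inherit.aes = FALSE, colour = "yellow", fill = NA,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax))
  }
  if (!is.null(boxes) && nrow(boxes) > 0) {
    p <- p + ggplot2::geom_rect(
      data = boxes, inherit.aes = FALSE, colour = "red", fill = NA,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax))
  }
  p
}

#' Map of burrows, mounds and the landscape boundary
#'
#' @param burrows,mounds Point tibbles (`x`, `y`).
#' @param landscape A `landscape_spec`.
#' @return A ggplot.
#' @export
plot_patterns <- function(burrows, mounds, landscape) {
  pts <- dplyr::bind_rows(
    dplyr::mutate(burrows[, c("x", "y")], what = "souslik burrow"),
    dplyr::mutate(mounds[, c("x", "y")], what = "mole mound"))
  ggplot2::ggplot() +
    ggplot2::geom_polygon(data = landscape$boundary,
                          ggplot2::aes(.data$x, .data$y),
                          fill = NA, colour = "grey40") +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(.data$x, .data$y, colour = .data$what),
                        size = 0.5) +
    ggplot2::scale_colour_manual(values = c("souslik burrow" = "#D55E00",
                                            "mole mound" = "#0072B2"),
                                 name = NULL) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

grid_to_df <- function(values, origin, cell_size) {
  nr <- nrow(values); nc <- ncol(values)
  tibble::tibble(
    x = rep(origin["x"] + (seq_len(nc) - 0.5) * cell_size, each = nr),
    y = rep(origin["y"] + (seq_len(nr) - 0.5) * cell_size, nc),
    value = as.vector(values))
}
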