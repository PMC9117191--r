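#' Define a study landscape
#'
#' A landscape is a simple planar polygon in local metric coordinates (the
#' field site boundary). All downstream stages — point-pattern generation,
#' zone construction, kernel density grids, imagery rendering — work inside
#' this boundary.
#'
#' @param boundary Data frame (or matrix) of polygon vertices with columns
#'   `x`, `y` in metres, in ring order, not closed.
#' @param crs_note Free-text note on the coordinate frame (kept as metadata;
#'   no CRS transformations are performed).
#' @return An object of class `landscape_spec`: the boundary as a tibble plus
#'   `total_area_ha`.
#' @examples
#' land <- landscape_rectangle(400, 250)
#' land$total_area_ha # 10 ha
#' @export
landscape_spec <- function(boundary, crs_note = "local metric, origin at SW corner") {
  xy <- as_xy(boundary)
  if (!polygon_is_simple(xy)) stop("boundary polygon is self-intersecting", call. = FALSE)
  area_m2 <- polygon_area_m2(xy)
  if (area_m2 <= 0) stop("boundary has zero area", call. = FALSE)
  structure(
    list(
      boundary = tibble::tibble(x = xy[, 1], y = xy[, 2]),
      total_area_ha = area_m2 / 1e4,
      crs_note = crs_note
    ),
    class = "landscape_spec"
  )
}

#' @rdname landscape_spec
#' @param width,height Rectangle dimensions in metres (origin at (0, 0)).
#' @export
landscape_rectangle <- function(width, height, crs_note = "local metric, origin at SW corner") {
  landscape_spec(
    tibble::tibble(x = c(0, width, width, 0), y = c(0, 0, height, height)),
    crs_note = crs_note
  )
}

#' @export
print.landscape_spec <- function(x, ...) {
  cat(sprintf("<landscape_spec> %d vertices, %.2f ha (%s)\n",
              nrow(x$boundary), x$total_area_ha, x$crs_note))
  invisible(x)
}

landscape_bbox <- function(landscape) {
  c(xmin = min(landscape$boundary$x), xmax = max(landscape$boundary$x),
    ymin = min(landscape$boundary$y), ymax = max(landscape$boundary$y))
}
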