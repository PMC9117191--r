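# Readers/writers for the interchange formats: point tables as CSV and
# GeoJSON, truth/prediction boxes as COCO-style JSON, rasters as TIFF with an
# ESRI world file carrying the affine geotransform, regions as GeoJSON
# MultiPolygons of grid-cell runs.

#' Write / read point sets
#'
#' @param points Tibble with `x`, `y` and optionally `species`.
#' @param path Output file path.
#' @name points_io
#' @export
write_points_csv <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname points_io
#' @export
read_points_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path))
}

#' @rdname points_io
#' @export
write_points_geojson <- function(points, path) {
  features <- purrr::pmap(points, function(x, y, ...) {
    props <- list(...)
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(x, y)),
         properties = if (length(props)) props else stats::setNames(list(), character(0)))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname points_io
#' @export
read_points_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  purrr::map_dfr(gj$features, function(f) {
    cc <- unlist(f$geometry$coordinates)
    props <- f$properties
    tibble::as_tibble(c(list(x = cc[1], y = cc[2]), props))
  })
}

#' Write boxes as COCO-style JSON
#'
#' Annotations carry `[x, y, width, height]` pixel boxes under category
#' `"mound"`; an `images` entry is written per distinct `image_id`.
#'
#' @param boxes Box tibble (optionally with `image_id`, `score`).
#' @param path Output path.
#' @export
write_boxes_coco <- function(boxes, path) {
  if (!"image_id" %in% names(boxes)) boxes$image_id <- 1L
  anns <- purrr::imap(split(boxes, seq_len(max(nrow(boxes), 0))), function(b, i) {
    a <- list(id = as.integer(i), image_id = b$image_id,
              category_id = 1L,
              bbox = c(b$xmin, b$ymin, b$xmax - b$xmin, b$ymax - b$ymin))
    if (!is.null(b$score) && !is.na(b$score)) a$score <- b$score
    a
  })
  coco <- list(
    images = purrr::map(unique(boxes$image_id),
                        function(id) list(id = id)),
    annotations = unname(anns),
    categories = list(list(id = 1L, name = "mound"))
  )
  jsonlite::write_json(coco, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read COCO-style JSON boxes
#' @param path COCO JSON path.
#' @return Box tibble with `image_id` and `score` (NA when absent).
#' @export
read_boxes_coco <- function(path) {
  coco <- jsonlite::read_json(path)
  purrr::map_dfr(coco$annotations, function(a) {
    bb <- unlist(a$bbox)
    tibble::tibble(xmin = bb[1], ymin = bb[2], xmax = bb[1] + bb[3],
                   ymax = bb[2] + bb[4],
                   score = if (is.null(a$score)) NA_real_ else a$score,
                   image_id = a$image_id)
  })
}

#' Write a raster as TIFF with a world file
#'
#' Writes the intensity matrix as a single-band TIFF and the affine
#' geotransform as an accompanying ESRI world file (`.tfw`), the sidecar
#' convention GIS tools read alongside plain TIFFs.
#'
#' @param ortho An `ortho_image`, or a matrix with `gsd` and `world`
#'   supplied.
#' @param path Output `.tif` path.
#' @param gsd,world Geotransform pieces when `ortho` is a bare matrix.
#' @export
write_raster_tiff <- function(ortho, path, gsd = NULL, world = NULL) {
  if (inherits(ortho, "ortho_image")) {
    px <- ortho$pixels; gsd <- ortho$gsd; world <- ortho$world
  } else {
    px <- ortho
    stopifnot(!is.null(gsd), !is.null(world))
  }
  tiff::writeTIFF(pmin(pmax(px, 0), 1), path)
  tfw <- sub("\\.tiff?$", ".tfw", path)
  # world file: x scale, rotations, negative y scale, centre of top-left px
  writeLines(format(c(gsd, 0, 0, -gsd,
                      world["xmin"] + gsd / 2, world["ymax"] - gsd / 2),
                    scientific = FALSE, trim = TRUE), tfw)
  invisible(path)
}

#' Read a TIFF raster with its world file
#' @param path `.tif` path (a `.tfw` sidecar must sit next to it).
#' @return An `ortho_image` (without truth boxes).
#' @export
read_raster_tiff <- function(path) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  tfw <- sub("\\.tiff?$", ".tfw", path)
  w <- as.numeric(readLines(tfw))
  gsd <- w[1]
  structure(
    list(pixels = px, gsd = gsd,
         world = c(xmin = w[5] - gsd / 2, ymax = w[6] + gsd / 2),
         truth = tibble::tibble(xmin = integer(0), ymin = integer(0),
                                xmax = integer(0), ymax = integer(0),
                                mound_x = numeric(0), mound_y = numeric(0),
                                score = numeric(0), source = character(0))),
    class = "ortho_image"
  )
}

#' Write a grid region as GeoJSON
#'
#' Each maximal horizontal run of region cells becomes one rectangle of a
#' MultiPolygon — a faithful, if unsimplified, vector rendering of the mask.
#'
#' @param region A `grid_region`.
#' @param path Output path.
#' @export
write_region_geojson <- function(region, path) {
  m <- region$mask; cs <- region$cell_size
  ox <- unname(region$origin["x"]); oy <- unname(region$origin["y"])
  polys <- list()
  for (i in seq_len(nrow(m))) {
    r <- rle(m[i, ])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      x0 <- ox + (starts[k] - 1) * cs; x1 <- ox + ends[k] * cs
      y0 <- oy + (i - 1) * cs; y1 <- oy + i * cs
      polys[[length(polys) + 1L]] <- list(list(
        c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0)))
    }
  }
  gj <- list(type = "Feature",
             geometry = list(type = "MultiPolygon", coordinates = polys),
             properties = list(area_ha = region$area_ha))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
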