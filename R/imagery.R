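# Synthetic orthoimagery: bright mound blobs on a darker correlated-noise
# sward, with exact ground-truth bounding boxes.
#
# Pixel convention (shared with the detection module): origin at the top-left
# of the raster, boxes are half-open [xmin, xmax) x [ymin, ymax) in 0-based
# pixel coordinates. World <-> pixel mapping is the affine geotransform
# x = xmin_w + px * gsd, y = ymax_w - py * gsd.

#' Imagery rendering parameters
#'
#' @param ground_sample_distance Metres per pixel (e.g. 0.02 for 2 cm).
#' @param mound_diameter_range Two-element range (m) of rendered mound
#'   diameters; molehills run about 0.15–0.50 m across.
#' @param mound_brightness_contrast How far (intensity units on a 0–1 scale)
#'   a mound's peak brightness sits above the 99th percentile of the
#'   background.
#' @param background_texture_scale Correlation length (m) of the background
#'   sward texture.
#' @param tile_size Tile edge in pixels for [export_tiles()].
#' @return An `image_spec` list.
#' @export
image_spec <- function(ground_sample_distance = 0.02,
                       mound_diameter_range = c(0.15, 0.50),
                       mound_brightness_contrast = 0.35,
                       background_texture_scale = 1,
                       tile_size = 256L) {
  stopifnot(
    ground_sample_distance > 0,
    length(mound_diameter_range) == 2,
    mound_diameter_range[1] > 0,
    mound_diameter_range[2] >= mound_diameter_range[1],
    mound_brightness_contrast >= 0,
    background_texture_scale > 0, tile_size > 0
  )
  structure(
    list(ground_sample_distance = ground_sample_distance,
         mound_diameter_range = mound_diameter_range,
         mound_brightness_contrast = mound_brightness_contrast,
         background_texture_scale = background_texture_scale,
         tile_size = as.integer(tile_size)),
    class = "image_spec"
  )
}

#' Render a synthetic orthoimage of mole mounds
#'
#' Each mound is drawn as a bright dome (a disc with a cosine-like falloff)
#' whose diameter is drawn uniformly from `mound_diameter_range`, over
#' correlated background noise. Truth boxes tightly bound the painted pixels
#' of each mound.
#'
#' @param mounds Tibble with mound coordinates `x`, `y` (m).
#' @param landscape A `landscape_spec`; its bounding box is the raster
#'   extent.
#' @param spec An `image_spec`. The ground sample distance must resolve the
#'   smallest mound diameter with at least 3 pixels.
#' @param noise `TRUE` (default) for textured background; `FALSE` renders a
#'   flat background (useful for detector oracles).
#' @param seed Integer seed for diameters and background noise.
#' @return An `ortho_image`: list with `pixels` (matrix, row 1 = top),
#'   `gsd`, `world` (xmin/ymax anchors of the geotransform), and `truth`, a
#'   tibble of boxes (`xmin`, `ymin`, `xmax`, `ymax` px, plus the source
#'   mound coordinates `mound_x`, `mound_y`).
#' @export
render_orthoimage <- function(mounds, landscape, spec = image_spec(),
                              noise = TRUE, seed = 1L) {
  stopifnot(inherits(landscape, "landscape_spec"), inherits(spec, "image_spec"))
  gsd <- spec$ground_sample_distance
  if (spec$mound_diameter_range[1] / gsd < 3) {
    stop("ground_sample_distance too coarse: smallest mound under 3 pixels",
         call. = FALSE)
  }
  withr::local_seed(seed)
  bb <- landscape_bbox(landscape)
  nc <- ceiling((bb["xmax"] - bb["xmin"]) / gsd)
  nr <- ceiling((bb["ymax"] - bb["ymin"]) / gsd)
  if (nr * nc > 5e7) stop("raster too large; render a smaller landscape window", call. = FALSE)

  if (noise) {
    bg <- matrix(stats::rnorm(nr * nc), nr, nc)
    # cap the blur kernel so it fits small rasters (texture cannot be
    # more correlated than the window is wide)
    sigma_px <- max(min(spec$background_texture_scale / gsd,
                        (min(nr, nc) - 1) / 8), 0.5)
    bg <- EBImage::gblur(bg, sigma = sigma_px)
    bg <- (bg - mean(bg)) / stats::sd(bg) * 0.04 + 0.30
    bg[bg < 0] <- 0
  } else {
    bg <- matrix(0.30, nr, nc)
  }
  p99 <- stats::quantile(bg, 0.99, names = FALSE)
  pixels <- bg
  boxes <- NULL
  if (nrow(mounds) > 0) {
    diam <- stats::runif(nrow(mounds), spec$mound_diameter_range[1],
                         spec$mound_diameter_range[2])
    rows <- vector("list", nrow(mounds))
    for (k in seq_len(nrow(mounds))) {
      R <- diam[k] / 2 / gsd                      # radius in pixels
      pxc <- (mounds$x[k] - bb["xmin"]) / gsd      # 0-based continuous col
      pyc <- (bb["ymax"] - mounds$y[k]) / gsd      # 0-based continuous row
      j0 <- max(0L, floor(pxc - R - 1)); j1 <- min(nc - 1L, ceiling(pxc + R + 1))
      i0 <- max(0L, floor(pyc - R - 1)); i1 <- min(nr - 1L, ceiling(pyc + R + 1))
      if (j1 < j0 || i1 < i0) next
      jj <- j0:j1; ii <- i0:i1
      d2 <- outer((ii + 0.5 - pyc)^2, (jj + 0.5 - pxc)^2, `+`)
      inside <- d2 <= R^2
      if (!any(inside)) next
      prof <- 0.35 + 0.65 * sqrt(pmax(0, 1 - d2 / R^2))
      val <- p99 + spec$mound_brightness_contrast * prof
      sub <- pixels[ii + 1L, jj + 1L, drop = FALSE]
      sub[inside] <- pmax(sub[inside], val[inside])
      pixels[ii + 1L, jj + 1L] <- sub
      hit_j <- jj[apply(inside, 2, any)]
      hit_i <- ii[apply(inside, 1, any)]
      rows[[k]] <- tibble::tibble(
        xmin = min(hit_j), ymin = min(hit_i),
        xmax = max(hit_j) + 1L, ymax = max(hit_i) + 1L,
        mound_x = mounds$x[k], mound_y = mounds$y[k])
    }
    boxes <- dplyr::bind_rows(rows)
  }
  if (is.null(boxes)) {
    boxes <- tibble::tibble(xmin = integer(0), ymin = integer(0),
                            xmax = integer(0), ymax = integer(0),
                            mound_x = numeric(0), mound_y = numeric(0))
  }
  boxes$score <- NA_real_
  boxes$source <- rep("truth", nrow(boxes))
  pixels[pixels > 1] <- 1
  structure(
    list(pixels = pixels, gsd = gsd,
         world = c(xmin = unname(bb["xmin"]), ymax = unname(bb["ymax"])),
         truth = boxes),
    class = "ortho_image"
  )
}

#' @export
print.ortho_image <- function(x, ...) {
  cat(sprintf("<ortho_image> %d x %d px at %.3g m/px, %d truth boxes\n",
              nrow(x$pixels), ncol(x$pixels), x$gsd, nrow(x$truth)))
  invisible(x)
}

#' Map pixel coordinates back to world coordinates
#'
#' @param ortho An `ortho_image`.
#' @param px,py 0-based pixel coordinates (continuous; a box centroid, say).
#' @return Tibble with world `x`, `y` in metres.
#' @export
pixel_to_world <- function(ortho, px, py) {
  tibble::tibble(x = ortho$world["xmin"] + px * ortho$gsd,
                 y = ortho$world["ymax"] - py * ortho$gsd)
}

#' Cut an orthoimage into labelled tiles
#'
#' The raster is cut into `tile_size` x `tile_size` tiles, padding the right
#' and bottom edges with background-like noise (values resampled from the
#' darker half of the raster). A truth box is assigned to every tile keeping
#' at least half of its area after clipping; if no tile keeps half (a box
#' straddling a tile corner), the single largest fragment is kept so every
#' box appears in at least one tile.
#'
#' @param ortho An `ortho_image`.
#' @param tile_size Tile edge, pixels.
#' @param pad_seed Seed for the padding noise.
#' @return Tibble with one row per tile: `tile_id`, `tile_row`, `tile_col`,
#'   `offset_x`, `offset_y` (px offsets of the tile origin), `pixels`
#'   (list-column of matrices) and `boxes` (list-column of tile-local box
#'   tibbles).
#' @export
export_tiles <- function(ortho, tile_size = 256L, pad_seed = 0L) {
  stopifnot(inherits(ortho, "ortho_image"), tile_size > 0)
  tile_size <- as.integer(tile_size)
  nr <- nrow(ortho$pixels); nc <- ncol(ortho$pixels)
  ntr <- ceiling(nr / tile_size); ntc <- ceiling(nc / tile_size)
  padded <- matrix(0, ntr * tile_size, ntc * tile_size)
  padded[seq_len(nr), seq_len(nc)] <- ortho$pixels
  if (ntr * tile_size > nr || ntc * tile_size > nc) {
    dark <- ortho$pixels[ortho$pixels <= stats::median(ortho$pixels)]
    n_pad <- length(padded) - nr * nc
    fill <- withr::with_seed(pad_seed, sample(dark, n_pad, replace = TRUE))
    mask <- matrix(TRUE, nrow(padded), ncol(padded))
    mask[seq_len(nr), seq_len(nc)] <- FALSE
    padded[mask] <- fill
  }
  truth <- ortho$truth
  box_area <- (truth$xmax - truth$xmin) * (truth$ymax - truth$ymin)

  assign_rows <- function(b) {
    # candidate tiles overlapped by box b; returns tibble(tile_row, tile_col, frac, clip)
    tc0 <- floor(truth$xmin[b] / tile_size); tc1 <- floor((truth$xmax[b] - 1) / tile_size)
    tr0 <- floor(truth$ymin[b] / tile_size); tr1 <- floor((truth$ymax[b] - 1) / tile_size)
    out <- list()
    for (tr in tr0:tr1) for (tc in tc0:tc1) {
      x0 <- tc * tile_size; y0 <- tr * tile_size
      cx0 <- max(truth$xmin[b], x0); cx1 <- min(truth$xmax[b], x0 + tile_size)
      cy0 <- max(truth$ymin[b], y0); cy1 <- min(truth$ymax[b], y0 + tile_size)
      if (cx1 <= cx0 || cy1 <= cy0) next
      out[[length(out) + 1L]] <- tibble::tibble(
        tile_row = tr, tile_col = tc,
        frac = (cx1 - cx0) * (cy1 - cy0) / box_area[b],
        xmin = cx0 - x0, ymin = cy0 - y0, xmax = cx1 - x0, ymax = cy1 - y0,
        box_id = b)
    }
    cand <- dplyr::bind_rows(out)
    keep <- cand[cand$frac >= 0.5, ]
    if (nrow(keep) == 0 && nrow(cand) > 0) {
      keep <- cand[order(-cand$frac, cand$tile_row, cand$tile_col), ][1, ]
    }
    keep
  }
  assigned <- if (nrow(truth) > 0) {
    dplyr::bind_rows(lapply(seq_len(nrow(truth)), assign_rows))
  } else {
    tibble::tibble(tile_row = integer(0), tile_col = integer(0), frac = numeric(0),
                   xmin = numeric(0), ymin = numeric(0), xmax = numeric(0),
                   ymax = numeric(0), box_id = integer(0))
  }

  grid <- tidyr::expand_grid(tile_row = 0:(ntr - 1), tile_col = 0:(ntc - 1))
  grid$tile_id <- seq_len(nrow(grid))
  grid$offset_x <- grid$tile_col * tile_size
  grid$offset_y <- grid$tile_row * tile_size
  grid$pixels <- purrr::map2(grid$tile_row, grid$tile_col, function(tr, tc) {
    padded[tr * tile_size + seq_len(tile_size), tc * tile_size + seq_len(tile_size)]
  })
  grid$boxes <- purrr::map2(grid$tile_row, grid$tile_col, function(tr, tc) {
    b <- assigned[assigned$tile_row == tr & assigned$tile_col == tc,
                  c("xmin", "ymin", "xmax", "ymax", "box_id")]
    tibble::as_tibble(b)
  })
  grid[, c("tile_id", "tile_row", "tile_col", "offset_x", "offset_y", "pixels", "boxes")]
}
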