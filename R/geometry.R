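# Minimal planar geometry on metric coordinates. All polygons are simple
# rings given as a two-column table of vertices (not closed); no CRS handling
# here — inputs must already be projected to a local metric frame.

#' Signed shoelace area of a polygon ring
#'
#' @param poly Data frame or matrix with columns `x`, `y` (vertices, metres,
#'   ring not repeated at the end).
#' @return Area in square metres (absolute value).
#' @keywords internal
polygon_area_m2 <- function(poly) {
  xy <- as_xy(poly)
  x <- xy[, 1]; y <- xy[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

as_xy <- function(poly) {
  m <- as.matrix(poly[, c("x", "y")])
  storage.mode(m) <- "double"
  if (nrow(m) < 3) stop("polygon needs at least 3 vertices", call. = FALSE)
  m
}

# Proper-crossing test for two closed segments, used only by the simplicity
# check; touching at shared ring vertices is not a crossing.
segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

#' Is a ring simple (non-self-intersecting)?
#' @keywords internal
polygon_is_simple <- function(poly) {
  xy <- as_xy(poly)
  n <- nrow(xy)
  idx <- cbind(seq_len(n), c(2:n, 1))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # skip adjacent edges (share a vertex)
      if (j == i + 1 || (i == 1 && j == n)) next
      if (segments_cross(xy[idx[i, 1], ], xy[idx[i, 2], ],
                         xy[idx[j, 1], ], xy[idx[j, 2], ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

#' Point-in-polygon test
#'
#' @param x,y Numeric vectors of point coordinates (metres).
#' @param poly Polygon ring (columns `x`, `y`).
#' @return Logical vector, `TRUE` for points inside the ring.
#' @keywords internal
point_in_polygon <- function(x, y, poly) {
  xy <- as_xy(poly)
  mgcv::in.out(rbind(xy, xy[1, , drop = FALSE]), cbind(x, y))
}

#' Uniform points inside a polygon by rejection from the bounding box
#' @keywords internal
runif_in_polygon <- function(n, poly, max_tries = 1000L) {
  xy <- as_xy(poly)
  xr <- range(xy[, 1]); yr <- range(xy[, 2])
  out_x <- numeric(0); out_y <- numeric(0)
  tries <- 0L
  while (length(out_x) < n && tries < max_tries) {
    m <- max(2L * (n - length(out_x)), 64L)
    px <- stats::runif(m, xr[1], xr[2])
    py <- stats::runif(m, yr[1], yr[2])
    keep <- point_in_polygon(px, py, poly)
    out_x <- c(out_x, px[keep]); out_y <- c(out_y, py[keep])
    tries <- tries + 1L
  }
  if (length(out_x) < n) stop("rejection sampling failed to fill the polygon", call. = FALSE)
  tibble::tibble(x = out_x[seq_len(n)], y = out_y[seq_len(n)])
}

# Distance from each point in (x, y) to its nearest neighbour among
# (bx, by); loops over whichever side is smaller so memory stays linear.
nearest_dist <- function(x, y, bx, by) {
  if (length(bx) == 0L) return(rep(Inf, length(x)))
  if (length(bx) <= length(x)) {
    d2 <- rep(Inf, length(x))
    for (k in seq_along(bx)) {
      dk <- (x - bx[k])^2 + (y - by[k])^2
      d2 <- pmin(d2, dk)
    }
  } else {
    d2 <- vapply(seq_along(x), function(i) {
      min((bx - x[i])^2 + (by - y[i])^2)
    }, numeric(1))
  }
  sqrt(d2)
}
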