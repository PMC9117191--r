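# Survey zones and spacing-constrained plot sampling.
#
# Three zones, following the field protocol: BURROW = 10 m^2 circular plots
# centred on inhabited nest burrows; COLONY = the 95% kernel-density
# isopleth of the burrow locations minus a 4 m exclusion disc around every
# burrow (limits autocorrelation with the BURROW plots); CONTROL = the
# landscape outside the full colony isopleth. Random plots keep a minimum
# centre spacing of 8 m within each zone so neighbouring plots never overlap.

#' Zone construction parameters
#'
#' @param plot_area Survey plot area, square metres (default 10).
#' @param colony_isopleth Mass fraction of the burrow kernel density that
#'   defines the colony (default 0.95).
#' @param burrow_exclusion_buffer Radius (m) cut out around each burrow when
#'   forming the COLONY zone (default 4).
#' @param min_plot_spacing Minimum distance (m) between random plot centres
#'   within a zone (default 8).
#' @param colony_kernel_radius Kernel radius (m) for the colony density
#'   surface. The field protocol does not fix this value, so it has no
#'   default and must be supplied.
#' @param cell_size Grid cell size (m) for the zone masks.
#' @return A `zone_config` list.
#' @export
zone_config <- function(plot_area = 10,
                        colony_isopleth = 0.95,
                        burrow_exclusion_buffer = 4,
                        min_plot_spacing = 8,
                        colony_kernel_radius = NULL,
                        cell_size = 1) {
  if (is.null(colony_kernel_radius)) {
    stop("colony_kernel_radius must be supplied (no protocol default exists)",
         call. = FALSE)
  }
  stopifnot(plot_area > 0, colony_isopleth > 0, colony_isopleth < 1,
            burrow_exclusion_buffer > 0, min_plot_spacing >= 0,
            colony_kernel_radius > 0, cell_size > 0)
  structure(
    list(plot_area = plot_area, colony_isopleth = colony_isopleth,
         burrow_exclusion_buffer = burrow_exclusion_buffer,
         min_plot_spacing = min_plot_spacing,
         colony_kernel_radius = colony_kernel_radius,
         cell_size = cell_size),
    class = "zone_config"
  )
}

#' Radius of a circular plot of given area
#'
#' A 10 m^2 plot has radius sqrt(10/pi) = 1.784 m, i.e. a diameter of
#' 3.57 m (3.56 when truncated to two decimals, the figure quoted in souslik
#' survey protocols).
#'
#' @param plot_area Plot area in square metres.
#' @return Radius in metres.
#' @examples
#' plot_radius(10)
#' @export
plot_radius <- function(plot_area) {
  if (any(plot_area <= 0)) stop("plot_area must be positive", call. = FALSE)
  sqrt(plot_area / pi)
}

#' Build the three survey zones from burrow locations
#'
#' @param burrows Tibble of burrow coordinates (`x`, `y`), at least 3 points,
#'   not all coincident.
#' @param landscape A `landscape_spec`.
#' @param cfg A `zone_config`.
#' @param year Scenario year attached to the BURROW plots.
#' @return A `zone_set`: list with `colony` and `control` (`grid_region`s on
#'   a common grid), `buffer_band` (the excluded ring inside the isopleth),
#'   `colony_isopleth` (the full isopleth region), and `burrow_plots`, a
#'   tibble of plots centred on the burrows (zone `"BURROW"`).
#' @export
build_zones <- function(burrows, landscape, cfg, year = NA_integer_) {
  stopifnot(inherits(landscape, "landscape_spec"), inherits(cfg, "zone_config"))
  if (nrow(burrows) < 3) stop("need at least 3 burrows to build zones", call. = FALSE)
  if (stats::sd(burrows$x) == 0 && stats::sd(burrows$y) == 0) {
    stop("degenerate burrow pattern: all points coincident", call. = FALSE)
  }
  land_region <- as_region(landscape, cfg$cell_size)
  grid <- density_grid(burrows, kernel_radius = cfg$colony_kernel_radius,
                       cell_size = cfg$cell_size, extent = landscape)
  iso <- isopleth_area(grid, cfg$colony_isopleth)
  iso_on_land <- region_on_grid(iso, land_region$origin, cfg$cell_size,
                                dim(land_region$mask))
  iso_on_land <- region_intersect(iso_on_land, land_region)

  # exclusion buffer: cells whose centre lies within the buffer of any burrow
  dims <- dim(land_region$mask)
  cx <- land_region$origin["x"] + (seq_len(dims[2]) - 0.5) * cfg$cell_size
  cy <- land_region$origin["y"] + (seq_len(dims[1]) - 0.5) * cfg$cell_size
  near <- matrix(FALSE, dims[1], dims[2])
  buf <- cfg$burrow_exclusion_buffer
  for (k in seq_len(nrow(burrows))) {
    jr <- which(abs(cx - burrows$x[k]) <= buf)
    ir <- which(abs(cy - burrows$y[k]) <= buf)
    if (!length(jr) || !length(ir)) next
    d2 <- outer((cy[ir] - burrows$y[k])^2, (cx[jr] - burrows$x[k])^2, `+`)
    near[ir, jr] <- near[ir, jr] | (d2 <= buf^2)
  }
  buffer_region <- grid_region(near, land_region$origin, cfg$cell_size)

  # the buffer is cut from both sampled zones: COLONY by protocol, and
  # CONTROL as well so that burrows whose locations fall outside their own
  # 95% isopleth (up to 5% of them) are still never sampled as random plots
  colony <- region_diff(iso_on_land, buffer_region)
  control <- region_diff(region_diff(land_region, iso_on_land), buffer_region)
  buffer_band <- region_intersect(land_region, buffer_region)

  r <- plot_radius(cfg$plot_area)
  burrow_plots <- tibble::tibble(
    x = burrows$x, y = burrows$y, radius_m = r,
    zone = "BURROW", year = as.integer(year), presence = NA_integer_)

  structure(
    list(colony = colony, control = control, buffer_band = buffer_band,
         colony_isopleth = iso_on_land, landscape_region = land_region,
         burrow_plots = burrow_plots, cfg = cfg),
    class = "zone_set"
  )
}

#' @export
print.zone_set <- function(x, ...) {
  cat(sprintf(
    "<zone_set> colony %.2f ha | control %.2f ha | buffer band %.2f ha | %d burrow plots\n",
    x$colony$area_ha, x$control$area_ha, x$buffer_band$area_ha,
    nrow(x$burrow_plots)))
  invisible(x)
}

#' Draw spacing-constrained random survey plots in a region
#'
#' Plot centres are sampled uniformly in the region by rejection, enforcing a
#' minimum pairwise spacing; each accepted point allows up to 10,000
#' proposals before the draw is declared infeasible.
#'
#' @param region A `grid_region` (a zone) or a `landscape_spec`.
#' @param n Number of plots.
#' @param cfg A `zone_config` (spacing and plot area are taken from it).
#' @param zone Zone label attached to the plots.
#' @param year Scenario year attached to the plots.
#' @param seed Integer seed.
#' @return Tibble of plots: `x`, `y`, `radius_m`, `zone`, `year`, `presence`
#'   (`NA` until scored).
#' @export
sample_plots <- function(region, n, cfg, zone = "CONTROL", year = NA_integer_,
                         seed = 1L) {
  if (inherits(region, "landscape_spec")) {
    region <- as_region(region, if (inherits(cfg, "zone_config")) cfg$cell_size else 1)
  }
  stopifnot(inherits(region, "grid_region"), n >= 1)
  if (region$area_ha <= 0) stop("region is empty", call. = FALSE)
  spacing <- cfg$min_plot_spacing
  withr::local_seed(seed)

  dims <- dim(region$mask)
  xr <- region$origin["x"] + c(0, dims[2] * region$cell_size)
  yr <- region$origin["y"] + c(0, dims[1] * region$cell_size)
  xs <- numeric(0); ys <- numeric(0)
  proposals <- 0L
  while (length(xs) < n) {
    if (proposals >= 10000L) {
      stop(sprintf("plot sampling infeasible: placed %d of %d at %.1f m spacing",
                   length(xs), n, spacing), call. = FALSE)
    }
    px <- stats::runif(1, xr[1], xr[2]); py <- stats::runif(1, yr[1], yr[2])
    proposals <- proposals + 1L
    if (!region_contains(region, px, py)) next
    if (spacing > 0 && length(xs) > 0 &&
        min(nearest_dist(px, py, xs, ys)) < spacing) next
    xs <- c(xs, px); ys <- c(ys, py)
    proposals <- 0L
  }
  tibble::tibble(x = xs, y = ys, radius_m = plot_radius(cfg$plot_area),
                 zone = zone, year = as.integer(year), presence = NA_integer_)
}
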