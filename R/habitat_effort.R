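# Mole-occupied area, habitat accounting, and transect survey effort.

#' Mole-occupied area from mound centroids
#'
#' The occupied area is the 95% isopleth of the fixed-radius kernel density
#' of the mound centroids; 5 m and 10 m radii are the conventional presets
#' (the larger radius always yields the larger area).
#'
#' @param mounds Tibble of mound centroids (`x`, `y`).
#' @param kernel_radius Kernel radius in metres (5 or 10 typically).
#' @param mass_fraction Isopleth mass fraction (default 0.95).
#' @param cell_size Grid cell size (default 1 m).
#' @param extent Optional extent (see [density_grid()]).
#' @return A `grid_region` (the isopleth).
#' @export
mole_occupied_area <- function(mounds, kernel_radius, mass_fraction = 0.95,
                               cell_size = 1, extent = NULL) {
  if (nrow(mounds) < 1) stop("need at least one mound", call. = FALSE)
  grid <- density_grid(mounds, kernel_radius = kernel_radius,
                       cell_size = cell_size, extent = extent)
  isopleth_area(grid, mass_fraction)
}

#' Burrow overlap with an occupied region
#'
#' @param burrows Tibble of burrow coordinates (`x`, `y`).
#' @param region A `grid_region` (closed membership: a burrow on a region
#'   cell counts as inside).
#' @return One-row tibble: `burrows_total`, `burrows_overlapping`,
#'   `overlap_fraction_pct` (to one decimal, the reporting convention for
#'   these percentages: 2 of 228 is 0.9%).
#' @export
burrow_overlap <- function(burrows, region) {
  if (nrow(burrows) == 0) stop("empty burrow set", call. = FALSE)
  inside <- region_contains(region, burrows$x, burrows$y)
  overlap_fraction(sum(inside), nrow(burrows))
}

#' @rdname burrow_overlap
#' @param count,total Printed integer counts, for reproducing reported
#'   percentages directly from a table.
#' @export
overlap_fraction <- function(count, total) {
  stopifnot(total > 0, count >= 0, count <= total)
  tibble::tibble(burrows_total = as.integer(total),
                 burrows_overlapping = as.integer(count),
                 overlap_fraction_pct = round(100 * count / total, 1))
}

#' Habitat account: what the mole leaves for the souslik
#'
#' @param total_area_ha Total grassland area, ha.
#' @param mole_area_ha Mole-occupied area, ha (a number or a `grid_region`).
#' @param kernel_radius Radius used to delineate the mole area (metadata).
#' @param burrows_total,burrows_overlapping Optional burrow overlap counts.
#' @return One-row tibble: `total_area_ha`, `mole_area_ha`,
#'   `remaining_area_ha` (= total − mole), `mole_fraction_pct` (integer
#'   percent, the reporting granularity: 15/105 is 14%, 40/105 is 38%), plus
#'   overlap columns when counts are given.
#' @export
habitat_account <- function(total_area_ha, mole_area_ha, kernel_radius = NA_real_,
                            burrows_total = NULL, burrows_overlapping = NULL) {
  if (inherits(mole_area_ha, "grid_region")) mole_area_ha <- mole_area_ha$area_ha
  stopifnot(total_area_ha > 0, mole_area_ha >= 0)
  out <- tibble::tibble(
    total_area_ha = total_area_ha,
    mole_area_ha = mole_area_ha,
    remaining_area_ha = total_area_ha - mole_area_ha,
    mole_fraction_pct = round(100 * mole_area_ha / total_area_ha),
    kernel_radius = kernel_radius
  )
  if (!is.null(burrows_total) && !is.null(burrows_overlapping)) {
    out <- dplyr::bind_cols(out, overlap_fraction(burrows_overlapping, burrows_total))
  }
  out
}

#' Transect survey effort configuration
#'
#' Defaults follow the standard souslik monitoring idealisation: an observer
#' walking 3 km/h inspecting a 5 m strip covers 1 ha in 40 min over a 2 km
#' route, and 10 ha is one person-day.
#'
#' @param walking_speed_kmh Observer speed, km/h.
#' @param strip_width_m Visually inspected strip width, m.
#' @param ha_per_day Area covered per person-day, ha.
#' @return An `effort_config` list.
#' @export
effort_config <- function(walking_speed_kmh = 3, strip_width_m = 5,
                          ha_per_day = 10) {
  stopifnot(walking_speed_kmh > 0, strip_width_m > 0, ha_per_day > 0)
  structure(list(walking_speed_kmh = walking_speed_kmh,
                 strip_width_m = strip_width_m, ha_per_day = ha_per_day),
            class = "effort_config")
}

#' Transect survey effort for an area
#'
#' Route per hectare is (10,000 m^2 / strip width) in km; time per hectare is
#' that route at walking speed. Totals scale linearly with area; person-days
#' are the ceiling of area over the daily coverage.
#'
#' @param area_ha Area to survey, ha.
#' @param cfg An `effort_config`.
#' @return One-row tibble: `area_ha`, `minutes_per_ha`, `route_km_per_ha`,
#'   `total_minutes`, `total_hours`, `total_route_km`, `person_days`.
#' @examples
#' effort_report(1)  # 40 min, 2 km with the defaults
#' effort_report(40) # ~27 h, 80 km, 4 person-days
#' @export
effort_report <- function(area_ha, cfg = effort_config()) {
  stopifnot(area_ha >= 0, inherits(cfg, "effort_config"))
  route_km_per_ha <- (1e4 / cfg$strip_width_m) / 1e3
  minutes_per_ha <- 60 * route_km_per_ha / cfg$walking_speed_kmh
  tibble::tibble(
    area_ha = area_ha,
    minutes_per_ha = minutes_per_ha,
    route_km_per_ha = route_km_per_ha,
    total_minutes = minutes_per_ha * area_ha,
    total_hours = minutes_per_ha * area_ha / 60,
    total_route_km = route_km_per_ha * area_ha,
    person_days = ceiling(area_ha / cfg$ha_per_day)
  )
}
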