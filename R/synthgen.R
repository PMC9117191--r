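# Synthetic two-species point patterns with controllable avoidance.
#
# Burrows: sequential-inhibition pattern (hard minimum spacing), optionally
# concentrated around colony nuclei so a colony isopleth occupies only part
# of the landscape. Mounds: stationary Matern-style cluster process (parents
# = mole territory centres, offspring = mounds strung near them), then
# independently thinned near burrows: a candidate mound within
# `avoidance_radius` of any burrow is deleted with probability
# `avoidance_strength`. Thinning is exactly calibratable, which is what the
# parameter-recovery tests need.

#' Parameters of the synthetic avoidance generator
#'
#' @param burrow_count Number of ground-squirrel nest burrows to place.
#' @param mound_base_intensity Unthinned mole-mound intensity, points per
#'   hectare.
#' @param avoidance_radius Radius (m) around each burrow within which
#'   candidate mounds are thinned.
#' @param avoidance_strength Probability in \[0, 1\] that a candidate mound
#'   within `avoidance_radius` of any burrow is deleted.
#' @param mound_cluster_size Mean mounds per mole tunnel cluster (Poisson).
#' @param mound_cluster_radius Radius (m) of the offspring disc around each
#'   cluster parent.
#' @param burrow_min_spacing Hard minimum distance (m) between burrows.
#' @param colony_nuclei Number of colony attraction centres for the burrow
#'   pattern; `0` places burrows uniformly over the landscape.
#' @param colony_spread Gaussian spread (m) of burrows around each nucleus.
#' @param seed Integer seed; the generator is deterministic given it.
#' @return An `avoidance_params` list.
#' @export
avoidance_params <- function(burrow_count = 228,
                             mound_base_intensity = 1225,
                             avoidance_radius = 30,
                             avoidance_strength = 0.945,
                             mound_cluster_size = 1050,
                             mound_cluster_radius = 45,
                             burrow_min_spacing = 10,
                             colony_nuclei = 3,
                             colony_spread = 180,
                             seed = 1L) {
  stopifnot(
    burrow_count >= 0, mound_base_intensity >= 0,
    avoidance_radius >= 0,
    avoidance_strength >= 0, avoidance_strength <= 1,
    mound_cluster_size > 0, mound_cluster_radius >= 0,
    burrow_min_spacing >= 0, colony_spread > 0
  )
  structure(
    list(burrow_count = as.integer(burrow_count),
         mound_base_intensity = mound_base_intensity,
         avoidance_radius = avoidance_radius,
         avoidance_strength = avoidance_strength,
         mound_cluster_size = mound_cluster_size,
         mound_cluster_radius = mound_cluster_radius,
         burrow_min_spacing = burrow_min_spacing,
         colony_nuclei = as.integer(colony_nuclei),
         colony_spread = colony_spread,
         seed = as.integer(seed)),
    class = "avoidance_params"
  )
}

#' Generate burrow and mound point patterns with known avoidance
#'
#' @param landscape A `landscape_spec`.
#' @param params An `avoidance_params` object.
#' @return A list with tibbles `burrows` and `mounds` (columns `x`, `y`,
#'   `species`); all points lie inside the landscape boundary.
#' @examples
#' land <- landscape_rectangle(300, 300)
#' pats <- generate_point_patterns(
#'   land, avoidance_params(burrow_count = 20, mound_base_intensity = 100,
#'                          colony_nuclei = 0, seed = 7))
#' nrow(pats$burrows)
#' @export
generate_point_patterns <- function(landscape, params) {
  stopifnot(inherits(landscape, "landscape_spec"), inherits(params, "avoidance_params"))
  withr::local_seed(params$seed)

  burrows <- place_burrows(landscape, params)
  mounds <- place_mounds(landscape, params, burrows)
  list(
    burrows = tibble::tibble(x = burrows$x, y = burrows$y, species = "souslik_burrow"),
    mounds = tibble::tibble(x = mounds$x, y = mounds$y, species = "mole_mound")
  )
}

place_burrows <- function(landscape, params) {
  n <- params$burrow_count
  if (n == 0L) return(tibble::tibble(x = numeric(0), y = numeric(0)))
  # packing sanity: n discs of radius spacing/2 cannot exceed the area
  area_m2 <- landscape$total_area_ha * 1e4
  if (params$burrow_min_spacing > 0 &&
      n * pi * (params$burrow_min_spacing / 2)^2 > area_m2) {
    stop(sprintf(
      "cannot place %d burrows at %.1f m minimum spacing in %.1f ha",
      n, params$burrow_min_spacing, landscape$total_area_ha), call. = FALSE)
  }
  nuclei <- if (params$colony_nuclei > 0) {
    runif_in_polygon(params$colony_nuclei, landscape$boundary)
  } else NULL

  # batched proposals, sequential (dart-throwing) acceptance under the
  # hard-core spacing
  xs <- numeric(n); ys <- numeric(n); placed <- 0L
  tries <- 0L; cap <- 10000L * n; sp2 <- params$burrow_min_spacing^2
  while (placed < n) {
    if (tries >= cap) {
      stop(sprintf("burrow placement failed: placed %d of %d at %.1f m spacing",
                   placed, n, params$burrow_min_spacing), call. = FALSE)
    }
    m <- max(4L * (n - placed), 64L)
    if (is.null(nuclei)) {
      bb <- landscape_bbox(landscape)
      px <- stats::runif(m, bb["xmin"], bb["xmax"])
      py <- stats::runif(m, bb["ymin"], bb["ymax"])
    } else {
      k <- sample.int(nrow(nuclei), m, replace = TRUE)
      px <- stats::rnorm(m, nuclei$x[k], params$colony_spread)
      py <- stats::rnorm(m, nuclei$y[k], params$colony_spread)
    }
    keep <- point_in_polygon(px, py, landscape$boundary)
    px <- px[keep]; py <- py[keep]
    for (i in seq_along(px)) {
      if (placed == n) break
      if (sp2 > 0 && placed > 0) {
        d2 <- (xs[seq_len(placed)] - px[i])^2 + (ys[seq_len(placed)] - py[i])^2
        if (min(d2) < sp2) next
      }
      placed <- placed + 1L
      xs[placed] <- px[i]; ys[placed] <- py[i]
    }
    tries <- tries + m
  }
  tibble::tibble(x = xs, y = ys)
}

place_mounds <- function(landscape, params, burrows) {
  empty <- tibble::tibble(x = numeric(0), y = numeric(0))
  if (params$mound_base_intensity <= 0) return(empty)
  bb <- landscape_bbox(landscape)
  # simulate the stationary cluster process on the bounding box expanded by
  # the cluster radius, then keep offspring inside the boundary: restricting
  # a stationary process keeps the expected count at intensity * area
  r <- params$mound_cluster_radius
  w <- c(bb["xmin"] - r, bb["xmax"] + r, bb["ymin"] - r, bb["ymax"] + r)
  win_area_ha <- (w[2] - w[1]) * (w[4] - w[3]) / 1e4
  kappa <- params$mound_base_intensity / params$mound_cluster_size # parents per ha
  n_par <- stats::rpois(1, kappa * win_area_ha)
  if (n_par == 0L) return(empty)
  px <- stats::runif(n_par, w[1], w[2])
  py <- stats::runif(n_par, w[3], w[4])
  n_off <- stats::rpois(n_par, params$mound_cluster_size)
  tot <- sum(n_off)
  if (tot == 0L) return(empty)
  parent <- rep.int(seq_len(n_par), n_off)
  # offspring uniform in the disc of radius r around the parent
  ang <- stats::runif(tot, 0, 2 * pi)
  rad <- r * sqrt(stats::runif(tot))
  mx <- px[parent] + rad * cos(ang)
  my <- py[parent] + rad * sin(ang)
  keep <- point_in_polygon(mx, my, landscape$boundary)
  mx <- mx[keep]; my <- my[keep]
  if (length(mx) == 0L) return(empty)
  # independent thinning near burrows
  if (params$avoidance_strength > 0 && params$avoidance_radius > 0 && nrow(burrows) > 0) {
    near <- nearest_dist(mx, my, burrows$x, burrows$y) <= params$avoidance_radius
    drop <- near & (stats::runif(length(mx)) < params$avoidance_strength)
    mx <- mx[!drop]; my <- my[!drop]
  }
  tibble::tibble(x = mx, y = my)
}
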