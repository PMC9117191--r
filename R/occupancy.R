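# Presence/absence scoring of survey plots and zone frequency tables.

#' Score mound presence on survey plots
#'
#' A plot scores presence 1 if at least one mound centroid lies within the
#' closed disc of the plot (distance to centre <= radius), else 0. Presence
#' is tri-state: `NA` (unscored) / 0 / 1; scoring never mixes unscored plots
#' silently into tables.
#'
#' @param plots Tibble of plots (`x`, `y`, `radius_m`, `zone`, `year`,
#'   `presence`).
#' @param mounds Tibble of mound centroids (`x`, `y`) in the same planar
#'   frame.
#' @return The plots tibble with `presence` filled in.
#' @examples
#' p <- tibble::tibble(x = 0, y = 0, radius_m = 1.78, zone = "BURROW",
#'                     year = 2019L, presence = NA_integer_)
#' score_plots(p, tibble::tibble(x = 1, y = 1))$presence
#' @export
score_plots <- function(plots, mounds) {
  stopifnot(all(c("x", "y", "radius_m") %in% names(plots)))
  if (nrow(plots) == 0) return(plots)
  if (nrow(mounds) == 0) {
    plots$presence <- 0L
    return(plots)
  }
  d <- nearest_dist(plots$x, plots$y, mounds$x, mounds$y)
  plots$presence <- as.integer(d <= plots$radius_m)
  plots
}

#' Per-zone, per-year presence frequency table
#'
#' @param plots Scored plots (no `NA` presence).
#' @return A tibble with one row per (zone, year): `n_plots`, `n_present`,
#'   `proportion` (exact fraction). Class `freq_table`.
#' @export
frequency_table <- function(plots) {
  if (anyNA(plots$presence)) stop("all plots must be scored before tabulation", call. = FALSE)
  out <- plots |>
    dplyr::group_by(.data$zone, .data$year) |>
    dplyr::summarise(
      n_plots = dplyr::n(),
      n_present = sum(.data$presence),
      proportion = sum(.data$presence) / dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$zone, .data$year)
  class(out) <- c("freq_table", class(out))
  out
}

#' Pooled zone means across years
#'
#' @param freq A `freq_table`.
#' @param weighted If `FALSE` (default) the pooled mean per zone is the
#'   unweighted mean of yearly proportions, matching how multi-year zone
#'   means are usually quoted alongside yearly ranges; if `TRUE`, the
#'   plot-weighted pooled proportion.
#' @return Tibble with `zone`, `mean_proportion`, `min_proportion`,
#'   `max_proportion`.
#' @export
zone_means <- function(freq, weighted = FALSE) {
  freq |>
    dplyr::group_by(.data$zone) |>
    dplyr::summarise(
      mean_proportion = if (weighted) sum(.data$n_present) / sum(.data$n_plots)
                        else mean(.data$proportion),
      min_proportion = min(.data$proportion),
      max_proportion = max(.data$proportion),
      .groups = "drop"
    )
}
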