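# Scenario orchestration: generate -> zones -> score -> stats ->
# detect-eval -> habitat/effort, from one validated config, with a
# reproducibility manifest.

#' Assemble and validate a scenario configuration
#'
#' @param name Scenario name.
#' @param master_seed Integer master seed. Per-stage seeds are derived as
#'   `master_seed + 100 * year_index + stage_offset` with fixed offsets
#'   (generate 11, colony plots 12, control plots 13, render 14, tile pad
#'   15), so one integer pins the whole run.
#' @param landscape A `landscape_spec`.
#' @param avoidance An `avoidance_params` (its `burrow_count` and `seed` are
#'   overridden per year).
#' @param zones A `zone_config` (must carry `colony_kernel_radius`).
#' @param years Tibble with `year`, `burrow_count`, `n_burrow_plots`,
#'   `n_colony_plots`, `n_control_plots`.
#' @param image An `image_spec`.
#' @param effort An `effort_config`.
#' @param mole_kernel_radii Kernel radii (m) for the mole occupied-area
#'   delineation.
#' @param render_window_m Edge (m) of the square window rendered to imagery
#'   for the detection stage.
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(name, master_seed, landscape, avoidance, zones,
                            years, image = image_spec(),
                            effort = effort_config(),
                            mole_kernel_radii = c(5, 10),
                            render_window_m = 40) {
  if (!inherits(landscape, "landscape_spec")) stop("landscape must be a landscape_spec", call. = FALSE)
  if (!inherits(avoidance, "avoidance_params")) stop("avoidance must be avoidance_params", call. = FALSE)
  if (!inherits(zones, "zone_config")) stop("zones must be a zone_config", call. = FALSE)
  if (is.null(zones$colony_kernel_radius)) stop("zone config lacks colony_kernel_radius", call. = FALSE)
  need <- c("year", "burrow_count", "n_burrow_plots", "n_colony_plots", "n_control_plots")
  if (!all(need %in% names(years))) {
    stop("years table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (any(years$n_burrow_plots > years$burrow_count)) {
    stop("n_burrow_plots cannot exceed burrow_count", call. = FALSE)
  }
  structure(
    list(name = name, master_seed = as.integer(master_seed),
         landscape = landscape, avoidance = avoidance, zones = zones,
         years = years, image = image, effort = effort,
         mole_kernel_radii = mole_kernel_radii,
         render_window_m = render_window_m),
    class = "scenario_config"
  )
}

stage_seed <- function(cfg, year_index, offset) {
  cfg$master_seed + 100L * year_index + offset
}

#' Run one simulated survey year
#'
#' Generates the point patterns, builds the zones, samples and scores the
#' plots, and fits the zone model with pairwise contrasts.
#'
#' @param cfg A `scenario_config`.
#' @param year_index Row of `cfg$years` to run.
#' @return List with `patterns`, `zones`, `plots` (scored), `freq`, `fit`,
#'   `contrasts`, `year`.
#' @export
run_year <- function(cfg, year_index) {
  yr <- cfg$years[year_index, ]
  params <- cfg$avoidance
  params$burrow_count <- yr$burrow_count
  params$seed <- stage_seed(cfg, year_index, 11L)
  pats <- generate_point_patterns(cfg$landscape, params)
  zs <- build_zones(pats$burrows, cfg$landscape, cfg$zones, year = yr$year)

  burrow_plots <- zs$burrow_plots
  if (yr$n_burrow_plots < nrow(burrow_plots)) {
    idx <- withr::with_seed(stage_seed(cfg, year_index, 16L),
                            sample.int(nrow(burrow_plots), yr$n_burrow_plots))
    burrow_plots <- burrow_plots[sort(idx), ]
  }
  colony_plots <- sample_plots(zs$colony, yr$n_colony_plots, cfg$zones,
                               zone = "COLONY", year = yr$year,
                               seed = stage_seed(cfg, year_index, 12L))
  control_plots <- sample_plots(zs$control, yr$n_control_plots, cfg$zones,
                                zone = "CONTROL", year = yr$year,
                                seed = stage_seed(cfg, year_index, 13L))
  plots <- dplyr::bind_rows(burrow_plots, colony_plots, control_plots)
  plots <- score_plots(plots, pats$mounds)
  fit <- fit_zone_model(plots)
  list(year = yr$year, patterns = pats, zones = zs, plots = plots,
       freq = frequency_table(plots), fit = fit,
       contrasts = pairwise_lsd(fit))
}

#' Run a full scenario and write its report bundle
#'
#' Runs every survey year, then — on the year with the most burrows — the
#' mole occupied-area / habitat / effort accounting and the imagery
#' rendering + blob-detection evaluation on a square window. All stage
#' outputs are written as CSV/JSON plus a manifest with the config hash and
#' derived seeds; a rerun with the same config reproduces the same manifest
#' hash.
#'
#' @param cfg A `scenario_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory results (`years`, `habitat`,
#'   `effort`, `detection`, `manifest`).
#' @export
run_scenario <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "scenario_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  years <- purrr::map(seq_len(nrow(cfg$years)), function(i) run_year(cfg, i))
  freq <- dplyr::bind_rows(purrr::map(years, "freq"))
  utils::write.csv(freq, file.path(out_dir, "frequency_table.csv"), row.names = FALSE)
  all_plots <- dplyr::bind_rows(purrr::map(years, "plots"))
  utils::write.csv(all_plots, file.path(out_dir, "plots.csv"), row.names = FALSE)
  contrasts <- dplyr::bind_rows(purrr::map(years, function(y) {
    dplyr::mutate(y$contrasts, year = y$year)
  }))
  utils::write.csv(contrasts, file.path(out_dir, "contrasts.csv"), row.names = FALSE)
  model_summaries <- dplyr::bind_rows(purrr::map(years, function(y) {
    dplyr::mutate(glance(y$fit), year = y$year)
  }))
  utils::write.csv(model_summaries, file.path(out_dir, "zone_models.csv"),
                   row.names = FALSE)

  # habitat / effort on the best-surveyed year
  main_i <- which.max(cfg$years$burrow_count)
  main <- years[[main_i]]
  write_points_csv(main$patterns$burrows, file.path(out_dir, "burrows.csv"))
  write_points_csv(main$patterns$mounds, file.path(out_dir, "mounds.csv"))
  write_points_geojson(main$patterns$burrows, file.path(out_dir, "burrows.geojson"))

  habitat <- purrr::map_dfr(cfg$mole_kernel_radii, function(r) {
    mole <- mole_occupied_area(main$patterns$mounds, kernel_radius = r,
                               extent = cfg$landscape)
    ov <- burrow_overlap(main$patterns$burrows, mole)
    habitat_account(cfg$landscape$total_area_ha, mole$area_ha, kernel_radius = r,
                    burrows_total = ov$burrows_total,
                    burrows_overlapping = ov$burrows_overlapping)
  })
  utils::write.csv(habitat, file.path(out_dir, "habitat_account.csv"), row.names = FALSE)
  effort <- dplyr::bind_rows(
    effort_report(1, cfg$effort),
    effort_report(max(habitat$mole_area_ha), cfg$effort))
  utils::write.csv(effort, file.path(out_dir, "effort_report.csv"), row.names = FALSE)

  detection <- run_detection_stage(cfg, main, out_dir)

  manifest <- scenario_manifest(cfg)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(years = years, freq = freq, contrasts = contrasts,
                 habitat = habitat, effort = effort, detection = detection,
                 manifest = manifest))
}

# Render a square window over the densest mound neighbourhood, detect blobs,
# evaluate against the rendered truth.
run_detection_stage <- function(cfg, main, out_dir) {
  mounds <- main$patterns$mounds
  if (nrow(mounds) == 0) return(NULL)
  w <- cfg$render_window_m
  cx <- stats::median(mounds$x); cy <- stats::median(mounds$y)
  win <- landscape_spec(tibble::tibble(
    x = cx + c(-w / 2, w / 2, w / 2, -w / 2),
    y = cy + c(-w / 2, -w / 2, w / 2, w / 2)))
  inside <- mounds$x >= cx - w / 2 & mounds$x <= cx + w / 2 &
    mounds$y >= cy - w / 2 & mounds$y <= cy + w / 2
  ortho <- render_orthoimage(mounds[inside, ], win, cfg$image,
                             seed = stage_seed(cfg, 0L, 14L))
  preds <- baseline_blob_detector(ortho)
  metrics <- evaluate_detections(preds, ortho$truth)
  write_raster_tiff(ortho, file.path(out_dir, "window.tif"))
  write_boxes_coco(ortho$truth, file.path(out_dir, "truth_boxes.json"))
  if (nrow(preds) > 0) write_boxes_coco(preds, file.path(out_dir, "pred_boxes.json"))
  utils::write.csv(metrics, file.path(out_dir, "detection_metrics.csv"),
                   row.names = FALSE)
  list(ortho = ortho, preds = preds, metrics = metrics)
}

scenario_manifest <- function(cfg) {
  cfg_txt <- paste(deparse(cfg[setdiff(names(cfg), "master_seed")]), collapse = "\n")
  tmp <- tempfile(); writeLines(cfg_txt, tmp)
  h <- unname(tools::md5sum(tmp)); unlink(tmp)
  list(
    scenario = cfg$name,
    config_hash = h,
    master_seed = cfg$master_seed,
    stage_seed_offsets = list(generate = 11L, colony_plots = 12L,
                              control_plots = 13L, render = 14L,
                              tile_pad = 15L, burrow_subset = 16L),
    package_version = as.character(utils::packageVersion("burrowscape"))
  )
}
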