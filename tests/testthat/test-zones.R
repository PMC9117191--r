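# Zone construction and spacing-constrained plot sampling.

test_that("plot radius follows the closed form", {
  expect_equal(plot_radius(10), sqrt(10 / pi), tolerance = 1e-12)
  expect_equal(plot_radius(pi), 1, tolerance = 1e-12)
  expect_equal(plot_radius(40), sqrt(40 / pi), tolerance = 1e-12)
  # a 10 m^2 plot: diameter 3.568 m, i.e. the protocol's "3.56" truncated
  expect_equal(trunc(2 * plot_radius(10) * 100) / 100, 3.56)
  expect_error(plot_radius(0))
})

make_zone_fixture <- function(seed = 21) {
  land <- landscape_rectangle(600, 500)
  p <- avoidance_params(burrow_count = 40, mound_base_intensity = 0,
                        colony_nuclei = 1, colony_spread = 70, seed = seed)
  burrows <- generate_point_patterns(land, p)$burrows
  cfg <- zone_config(colony_kernel_radius = 40)
  list(land = land, burrows = burrows, cfg = cfg,
       zones = build_zones(burrows, land, cfg, year = 2019))
}

test_that("colony, control and buffer band partition the landscape", {
  f <- make_zone_fixture()
  z <- f$zones
  total <- z$colony$area_ha + z$control$area_ha + z$buffer_band$area_ha
  expect_lt(abs(total - z$landscape_region$area_ha) / z$landscape_region$area_ha,
            0.005)
  # pairwise disjoint by construction on the shared grid
  expect_equal(sum(z$colony$mask & z$control$mask), 0)
  expect_equal(sum(z$colony$mask & z$buffer_band$mask), 0)
})

test_that("burrow plot centres sit in the excluded buffer, not in colony or control", {
  f <- make_zone_fixture()
  z <- f$zones
  expect_false(any(region_contains(z$colony, f$burrows$x, f$burrows$y)))
  expect_false(any(region_contains(z$control, f$burrows$x, f$burrows$y)))
})

test_that("colony isopleth area agrees with a fine-grid oracle for a tight cluster", {
  land <- landscape_rectangle(300, 300)
  set.seed(8)
  burrows <- tibble::tibble(x = 150 + runif(10, -15, 15),
                            y = 150 + runif(10, -15, 15))
  cfg <- zone_config(colony_kernel_radius = 20, cell_size = 1)
  z <- build_zones(burrows, land, cfg)
  oracle_m2 <- isopleth_area_oracle(burrows, kernel_radius = 20,
                                    mass_fraction = 0.95, cell = 0.25)
  expect_lt(abs(z$colony_isopleth$area_ha * 1e4 - oracle_m2) / oracle_m2, 0.10)
})

test_that("degenerate burrow patterns are rejected", {
  land <- landscape_rectangle(100, 100)
  cfg <- zone_config(colony_kernel_radius = 20)
  expect_error(build_zones(tibble::tibble(x = c(1, 2), y = c(1, 2)), land, cfg),
               "at least 3")
  same <- tibble::tibble(x = rep(50, 5), y = rep(50, 5))
  expect_error(build_zones(same, land, cfg), "coincident")
})

test_that("sampled plots respect the minimum spacing, checked exhaustively", {
  f <- make_zone_fixture()
  plots <- sample_plots(f$zones$control, 100, f$cfg, zone = "CONTROL", seed = 5)
  expect_equal(nrow(plots), 100)
  expect_true(all(region_contains(f$zones$control, plots$x, plots$y)))
  d <- as.matrix(stats::dist(cbind(plots$x, plots$y)))
  diag(d) <- Inf
  expect_gte(min(d), f$cfg$min_plot_spacing)
})

test_that("a single plot always fits in a non-empty region", {
  f <- make_zone_fixture()
  expect_equal(nrow(sample_plots(f$zones$colony, 1, f$cfg, seed = 3)), 1)
})

test_that("impossible disc packings fail with a count of placed points", {
  land <- landscape_rectangle(10, 10)
  cfg <- zone_config(colony_kernel_radius = 20)
  expect_error(sample_plots(as_region(land, 1), 5, cfg, seed = 2),
               "placed \\d+ of 5")
})

test_that("without the spacing constraint, centres are uniform (chi-square over 4x4)", {
  land <- landscape_rectangle(400, 400)
  region <- as_region(land, 1)
  cfg <- zone_config(colony_kernel_radius = 20, min_plot_spacing = 0)
  pass <- vapply(1:100, function(s) {
    pl <- sample_plots(region, 200, cfg, seed = s)
    cells <- table(factor(pmin(floor(pl$x / 100), 3), levels = 0:3),
                   factor(pmin(floor(pl$y / 100), 3), levels = 0:3))
    stats::chisq.test(as.vector(cells))$p.value > 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("plot sampling is deterministic in the seed", {
  f <- make_zone_fixture()
  a <- sample_plots(f$zones$control, 30, f$cfg, seed = 77)
  b <- sample_plots(f$zones$control, 30, f$cfg, seed = 77)
  expect_identical(a, b)
})
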