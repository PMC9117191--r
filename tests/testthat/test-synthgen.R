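# Point-pattern generator: boundary containment, thinning semantics,
# intensity calibration, determinism.

test_that("zero mound intensity yields an empty mound set", {
  land <- landscape_rectangle(200, 200)
  p <- avoidance_params(burrow_count = 5, mound_base_intensity = 0,
                        colony_nuclei = 0, seed = 1)
  pats <- generate_point_patterns(land, p)
  expect_equal(nrow(pats$mounds), 0)
  expect_equal(nrow(pats$burrows), 5)
})

test_that("all generated points fall inside the boundary, several seeds", {
  land <- landscape_spec(tibble::tibble(x = c(0, 300, 380, 150, 0),
                                        y = c(0, 40, 260, 300, 180)))
  for (s in 1:5) {
    p <- avoidance_params(burrow_count = 15, mound_base_intensity = 300,
                          mound_cluster_size = 6, mound_cluster_radius = 10,
                          colony_nuclei = 0, seed = s)
    pats <- generate_point_patterns(land, p)
    expect_true(all(point_in_polygon(pats$burrows$x, pats$burrows$y, land$boundary)))
    expect_true(all(point_in_polygon(pats$mounds$x, pats$mounds$y, land$boundary)))
  }
})

test_that("burrow hard-core spacing is respected", {
  land <- landscape_rectangle(400, 400)
  p <- avoidance_params(burrow_count = 60, colony_nuclei = 0,
                        burrow_min_spacing = 12, mound_base_intensity = 0,
                        seed = 11)
  b <- generate_point_patterns(land, p)$burrows
  d <- as.matrix(stats::dist(cbind(b$x, b$y)))
  diag(d) <- Inf
  expect_gte(min(d), 12)
})

test_that("an overfull boundary fails loudly instead of silently truncating", {
  land <- landscape_rectangle(30, 30)
  p <- avoidance_params(burrow_count = 100, burrow_min_spacing = 10,
                        colony_nuclei = 0, seed = 1)
  expect_error(generate_point_patterns(land, p), "cannot place")
})

test_that("with no avoidance the mean mound count matches intensity x area", {
  land <- landscape_rectangle(100, 100) # 1 ha
  counts <- vapply(1:200, function(s) {
    p <- avoidance_params(burrow_count = 3, mound_base_intensity = 200,
                          mound_cluster_size = 5, mound_cluster_radius = 10,
                          avoidance_strength = 0, colony_nuclei = 0, seed = s)
    nrow(generate_point_patterns(land, p)$mounds)
  }, numeric(1))
  expected <- 200 * 1 # intensity x area(ha)
  mc_se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * mc_se)
})

test_that("full-strength thinning leaves no mound within the avoidance radius", {
  land <- landscape_rectangle(200, 200)
  for (s in 1:10) {
    p <- avoidance_params(burrow_count = 10, mound_base_intensity = 400,
                          mound_cluster_size = 5, mound_cluster_radius = 8,
                          avoidance_strength = 1, avoidance_radius = 5,
                          colony_nuclei = 0, seed = s)
    pats <- generate_point_patterns(land, p)
    if (nrow(pats$mounds) == 0) next
    d <- nearest_dist(pats$mounds$x, pats$mounds$y,
                      pats$burrows$x, pats$burrows$y)
    expect_gt(min(d), 5)
  }
})

test_that("presence at burrows decreases monotonically in avoidance strength", {
  land <- landscape_rectangle(200, 200)
  strengths <- c(0, 0.25, 0.5, 0.75, 1)
  mean_presence <- vapply(strengths, function(st) {
    pres <- vapply(1:60, function(s) {
      p <- avoidance_params(burrow_count = 12, mound_base_intensity = 800,
                            mound_cluster_size = 40, mound_cluster_radius = 20,
                            avoidance_strength = st, avoidance_radius = 15,
                            colony_nuclei = 0, seed = s)
      pats <- generate_point_patterns(land, p)
      plots <- tibble::tibble(x = pats$burrows$x, y = pats$burrows$y,
                              radius_m = plot_radius(10), zone = "BURROW",
                              year = 1L, presence = NA_integer_)
      mean(score_plots(plots, pats$mounds)$presence)
    }, numeric(1))
    mean(pres)
  }, numeric(1))
  expect_true(all(diff(mean_presence) < 0))
})

test_that("the same seed reproduces identical point sets", {
  land <- landscape_rectangle(250, 250)
  p <- avoidance_params(burrow_count = 10, mound_base_intensity = 150,
                        colony_nuclei = 2, colony_spread = 60, seed = 99)
  a <- generate_point_patterns(land, p)
  b <- generate_point_patterns(land, p)
  expect_identical(a, b)
})

test_that("avoidance parameter validation rejects out-of-range values", {
  expect_error(avoidance_params(avoidance_strength = 1.2))
  expect_error(avoidance_params(mound_base_intensity = -1))
})
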