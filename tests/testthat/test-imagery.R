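# Orthoimage rendering, geotransform round trips, and tiling.

test_that("a 0.30 m mound at 2 cm gsd paints a box 15 px wide, within 1 px", {
  land <- landscape_rectangle(4, 4)
  spec <- image_spec(mound_diameter_range = c(0.30, 0.30))
  ortho <- render_orthoimage(tibble::tibble(x = 2, y = 2), land, spec,
                             noise = FALSE, seed = 1)
  expect_equal(nrow(ortho$truth), 1)
  w <- ortho$truth$xmax - ortho$truth$xmin
  h <- ortho$truth$ymax - ortho$truth$ymin
  expect_lte(abs(w - 15), 1)
  expect_lte(abs(h - 15), 1)
})

test_that("zero mounds give a valid background-only raster and empty truth", {
  land <- landscape_rectangle(5, 5)
  ortho <- render_orthoimage(tibble::tibble(x = numeric(0), y = numeric(0)),
                             land, image_spec(), seed = 2)
  expect_equal(nrow(ortho$truth), 0)
  expect_true(all(is.finite(ortho$pixels)))
  expect_equal(dim(ortho$pixels), c(250, 250))
})

test_that("every interior mound yields exactly one truth box", {
  land <- landscape_rectangle(30, 30)
  set.seed(9)
  mounds <- tibble::tibble(x = runif(100, 1, 29), y = runif(100, 1, 29))
  ortho <- render_orthoimage(mounds, land, image_spec(), noise = FALSE, seed = 3)
  expect_equal(nrow(ortho$truth), 100)
})

test_that("truth box centroids back-project to the mound within one gsd", {
  land <- landscape_rectangle(20, 20)
  set.seed(5)
  mounds <- tibble::tibble(x = runif(25, 1, 19), y = runif(25, 1, 19))
  ortho <- render_orthoimage(mounds, land, image_spec(), noise = FALSE, seed = 5)
  ctr <- pixel_to_world(ortho,
                        (ortho$truth$xmin + ortho$truth$xmax) / 2,
                        (ortho$truth$ymin + ortho$truth$ymax) / 2)
  err <- sqrt((ctr$x - ortho$truth$mound_x)^2 + (ctr$y - ortho$truth$mound_y)^2)
  expect_lt(max(err), ortho$gsd + 1e-9)
})

test_that("rendering refuses a gsd that cannot resolve the smallest mound", {
  land <- landscape_rectangle(10, 10)
  spec <- image_spec(ground_sample_distance = 0.10,
                     mound_diameter_range = c(0.15, 0.50))
  expect_error(render_orthoimage(tibble::tibble(x = 5, y = 5), land, spec),
               "3 pixels")
})

test_that("rendering is deterministic in the seed", {
  land <- landscape_rectangle(8, 8)
  m <- tibble::tibble(x = c(2, 6), y = c(3, 5))
  a <- render_orthoimage(m, land, image_spec(), seed = 7)
  b <- render_orthoimage(m, land, image_spec(), seed = 7)
  expect_identical(a$pixels, b$pixels)
  expect_identical(a$truth, b$truth)
})

test_that("a 512x512 raster cuts into 4 tiles of 256", {
  land <- landscape_rectangle(512 * 0.02, 512 * 0.02)
  ortho <- render_orthoimage(tibble::tibble(x = numeric(0), y = numeric(0)),
                             land, image_spec(), seed = 1)
  tiles <- export_tiles(ortho, 256)
  expect_equal(nrow(tiles), 4)
  expect_true(all(vapply(tiles$pixels, function(p) all(dim(p) == 256), logical(1))))
})

test_that("a box fully inside one tile appears exactly once, translated", {
  land <- landscape_rectangle(512 * 0.02, 512 * 0.02)
  # one mound inside the bottom-right tile
  ortho <- render_orthoimage(tibble::tibble(x = 8, y = 2), land, image_spec(),
                             noise = FALSE, seed = 1)
  tiles <- export_tiles(ortho, 256)
  counts <- vapply(tiles$boxes, nrow, integer(1))
  expect_equal(sum(counts), 1)
  hit <- tiles[counts == 1, ]
  tb <- hit$boxes[[1]]
  expect_equal(tb$xmin + hit$offset_x, ortho$truth$xmin)
  expect_equal(tb$ymin + hit$offset_y, ortho$truth$ymin)
})

test_that("a 60/40 straddling box is kept only in the 60% tile", {
  ortho <- structure(
    list(pixels = matrix(0.3, 100, 200), gsd = 0.02,
         world = c(xmin = 0, ymax = 2),
         truth = tibble::tibble(xmin = 94, ymin = 10, xmax = 104, ymax = 20,
                                mound_x = NA_real_, mound_y = NA_real_,
                                score = NA_real_, source = "truth")),
    class = "ortho_image")
  tiles <- export_tiles(ortho, 100)
  counts <- vapply(tiles$boxes, nrow, integer(1))
  expect_equal(sum(counts), 1)
  keeper <- tiles[counts == 1, ]
  expect_equal(keeper$tile_col, 0) # the left tile holds 6 of 10 columns
  expect_equal(keeper$boxes[[1]]$xmax, 100)
})

test_that("every truth box lands in at least one tile, even corner straddlers", {
  ortho <- structure(
    list(pixels = matrix(0.3, 200, 200), gsd = 0.02,
         world = c(xmin = 0, ymax = 4),
         truth = tibble::tibble(
           xmin = c(95, 40), ymin = c(95, 40), xmax = c(105, 50),
           ymax = c(105, 50), mound_x = NA_real_, mound_y = NA_real_,
           score = NA_real_, source = "truth")),
    class = "ortho_image")
  tiles <- export_tiles(ortho, 100) # first box splits 25/25/25/25 across 4 tiles
  all_ids <- unlist(purrr::map(tiles$boxes, "box_id"))
  expect_setequal(unique(all_ids), c(1, 2))
  expect_equal(sum(all_ids == 1), 1) # largest-fragment fallback keeps one copy
})

test_that("a tile size larger than the raster yields a single padded tile", {
  land <- landscape_rectangle(2, 2)
  ortho <- render_orthoimage(tibble::tibble(x = 1, y = 1), land, image_spec(),
                             seed = 3)
  tiles <- export_tiles(ortho, 256)
  expect_equal(nrow(tiles), 1)
  expect_equal(dim(tiles$pixels[[1]]), c(256, 256))
})
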