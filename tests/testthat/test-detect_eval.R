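# IoU, greedy matching with the duplicate rule, pooled metrics, AP, and the
# blob-detector baseline.

bx <- function(x0, y0, x1, y1, score = NA_real_) {
  detection_boxes(x0, y0, x1, y1, score = score)
}

test_that("IoU basics and the pixel-count oracle agree", {
  a <- bx(0, 0, 2, 2)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, bx(5, 5, 6, 6)), 0)
  b <- bx(1, 1, 3, 3)
  expect_equal(box_iou(a, b), 1 / 7, tolerance = 1e-12)
  expect_equal(box_iou(a, b), iou_pixel_oracle(a, b), tolerance = 1e-6)
  # symmetry and range on random boxes
  set.seed(31)
  for (k in 1:20) {
    p <- bx(runif(1, 0, 5), runif(1, 0, 5), runif(1, 6, 10), runif(1, 6, 10))
    q <- bx(runif(1, 0, 5), runif(1, 0, 5), runif(1, 6, 10), runif(1, 6, 10))
    ij <- box_iou(p, q)
    expect_equal(ij, box_iou(q, p))
    expect_gte(ij, 0); expect_lte(ij, 1)
  }
  expect_error(box_iou(bx(0, 0, 1, 1), list(xmin = 2, ymin = 2, xmax = 2, ymax = 3)),
               "degenerate")
})

test_that("one exact prediction is a TP; duplicates become FPs", {
  truth <- bx(10, 10, 20, 20)
  one <- bx(10, 10, 20, 20, score = 0.9)
  m <- match_detections(one, truth)
  expect_equal(list(m$tp, m$fp, m$fn), list(1L, 0L, 0L))
  two <- detection_boxes(c(10, 10), c(10, 10), c(20, 20), c(20, 20),
                         score = c(0.9, 0.8))
  m2 <- match_detections(two, truth)
  expect_equal(list(m2$tp, m2$fp, m2$fn), list(1L, 1L, 0L))
})

test_that("IoU exactly at the threshold counts as FP, strictly above as TP", {
  truth <- bx(0, 0, 10, 10)
  half <- bx(0, 0, 10, 5, score = 1) # IoU exactly 0.5
  m <- match_detections(half, truth, iou_threshold = 0.5)
  expect_equal(list(m$tp, m$fp, m$fn), list(0L, 1L, 1L))
  above <- bx(0, 0, 10, 6, score = 1) # IoU 0.6
  m2 <- match_detections(above, truth, iou_threshold = 0.5)
  expect_equal(m2$tp, 1L)
})

test_that("greedy matching equals exhaustive assignment when every pair clears the bar", {
  set.seed(8)
  for (rep in 1:30) {
    base <- c(runif(1, 0, 40), runif(1, 0, 40))
    nt <- sample(1:3, 1); np <- sample(1:3, 1)
    jit <- function(n) tibble::tibble(
      xmin = base[1] + runif(n, -0.5, 0.5), ymin = base[2] + runif(n, -0.5, 0.5))
    tr <- jit(nt); pr <- jit(np)
    truths <- detection_boxes(tr$xmin, tr$ymin, tr$xmin + 10, tr$ymin + 10)
    preds <- detection_boxes(pr$xmin, pr$ymin, pr$xmin + 10, pr$ymin + 10,
                             score = runif(np))
    m <- match_detections(preds, truths)
    expect_equal(m$tp, optimal_match_oracle(preds, truths))
  }
})

test_that("greedy matching can drop one match in a crossed adversarial case", {
  # pred A overlaps both truths, pred B only the first; greedy lets A take
  # truth 1 and strands B, one short of the optimal assignment
  truths <- detection_boxes(c(0, 8), c(0, 0), c(20, 28), c(10, 10))
  preds <- detection_boxes(c(2, 0), c(0, 0), c(22, 20), c(10, 10),
                           score = c(0.9, 0.5))
  m <- match_detections(preds, truths)
  expect_equal(m$tp, 1L)
  expect_equal(optimal_match_oracle(preds, truths), 2L)
})

test_that("pooled metrics follow the printed formulas and the F1 identity", {
  # tp=2, fp=1, fn=1 -> precision = recall = f1 = 2/3
  truths <- detection_boxes(c(0, 20, 40), c(0, 0, 0), c(10, 30, 50), c(10, 10, 10))
  preds <- detection_boxes(c(0, 20, 60), c(0, 0, 0), c(10, 30, 70), c(10, 10, 10),
                           score = c(0.9, 0.8, 0.7))
  ev <- evaluate_detections(preds, truths)
  expect_equal(ev$tp, 2L); expect_equal(ev$fp, 1L); expect_equal(ev$fn, 1L)
  expect_equal(ev$precision, 2 / 3)
  expect_equal(ev$recall, 2 / 3)
  expect_equal(ev$f1, 2 / 3)
  expect_equal(ev$f1, 2 * ev$tp / (2 * ev$tp + ev$fp + ev$fn))
  expect_equal(ev$f1, 2 * ev$precision * ev$recall / (ev$precision + ev$recall))
})

test_that("a perfect detector scores 1 everywhere; a silent one has recall 0", {
  truths <- detection_boxes(c(0, 20), c(0, 0), c(10, 30), c(10, 10))
  perfect <- detection_boxes(c(0, 20), c(0, 0), c(10, 30), c(10, 10),
                             score = c(1, 1))
  ev <- evaluate_detections(perfect, truths)
  expect_equal(c(ev$precision, ev$recall, ev$f1, ev$average_precision),
               c(1, 1, 1, 1))
  silent <- detection_boxes(numeric(0), numeric(0), numeric(0), numeric(0))
  ev0 <- evaluate_detections(silent, truths)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$fn, 2L)
  # no truths, no predictions: undefined, not zero
  evNA <- evaluate_detections(silent, silent)
  expect_true(is.na(evNA$precision) && is.na(evNA$recall) && is.na(evNA$f1))
})

test_that("metrics pool per tile and are invariant to tile order", {
  t1 <- detection_boxes(c(0, 20), c(0, 0), c(10, 30), c(10, 10))
  t1$image_id <- 1L
  t2 <- detection_boxes(5, 5, 15, 15); t2$image_id <- 2L
  p1 <- detection_boxes(0, 0, 10, 10, score = 0.9); p1$image_id <- 1L
  p2 <- detection_boxes(50, 50, 60, 60, score = 0.8); p2$image_id <- 2L
  fwd <- evaluate_detections(dplyr::bind_rows(p1, p2), dplyr::bind_rows(t1, t2))
  rev <- evaluate_detections(dplyr::bind_rows(p2, p1), dplyr::bind_rows(t2, t1))
  expect_equal(fwd, rev)
  expect_equal(fwd$tp, 1L); expect_equal(fwd$fp, 1L); expect_equal(fwd$fn, 2L)
})

test_that("AP is invariant under strictly monotone score transforms", {
  set.seed(12)
  truths <- detection_boxes(seq(0, 90, 10), 0, seq(8, 98, 10), 8)
  keep <- sample(10, 6)
  preds <- dplyr::bind_rows(
    truths[keep, c("xmin", "ymin", "xmax", "ymax")],
    tibble::tibble(xmin = c(200, 300), ymin = 0, xmax = c(208, 308), ymax = 8))
  preds <- detection_boxes(preds$xmin, preds$ymin, preds$xmax, preds$ymax,
                           score = runif(8, 0.2, 0.9))
  ap1 <- evaluate_detections(preds, truths)$average_precision
  preds2 <- dplyr::mutate(preds, score = score^3)
  ap2 <- evaluate_detections(preds2, truths)$average_precision
  expect_equal(ap1, ap2, tolerance = 1e-12)
  expect_true(ap1 > 0 && ap1 < 1)
})

test_that("the blob detector finds every mound on a noise-free render", {
  land <- landscape_rectangle(10, 10)
  mounds <- tibble::tibble(x = c(2, 5, 8, 3.5, 7), y = c(2, 5, 8, 7.5, 2.5))
  ortho <- render_orthoimage(mounds, land, image_spec(), noise = FALSE, seed = 4)
  preds <- baseline_blob_detector(ortho)
  expect_equal(nrow(preds), 5)
  ev <- evaluate_detections(preds, ortho$truth)
  expect_equal(ev$tp, 5L)
  expect_equal(ev$fp, 0L)
})

test_that("undersized components are rejected by the diameter prior", {
  px <- matrix(0.3, 100, 100)
  px[50:51, 50:51] <- 0.9 # 2 px blob = 4 cm at 2 cm gsd, below the 15 cm prior
  preds <- baseline_blob_detector(px, gsd = 0.02)
  expect_equal(nrow(preds), 0)
})

test_that("recall stays high on the standard noisy synthetic benchmark", {
  land <- landscape_rectangle(20, 20)
  set.seed(606)
  mounds <- tibble::tibble(x = runif(12, 2, 18), y = runif(12, 2, 18))
  ortho <- render_orthoimage(mounds, land, image_spec(), noise = TRUE, seed = 606)
  preds <- baseline_blob_detector(ortho)
  ev <- evaluate_detections(preds, ortho$truth)
  expect_gte(ev$recall, 0.7)
})
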