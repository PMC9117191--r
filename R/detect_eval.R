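# Bounding-box detection evaluation: IoU, greedy matching with the
# duplicate-detection-as-FP rule, pooled precision/recall/F1 and all-point
# interpolated average precision, plus a classical blob-detector baseline.
#
# Conventions: boxes are half-open [xmin, xmax) x [ymin, ymax) in pixels;
# a true positive requires IoU strictly greater than the threshold (0.5 by
# default) — IoU exactly at the threshold counts as a false positive.

#' Build a box tibble
#'
#' @param xmin,ymin,xmax,ymax Box edges in pixels, half-open.
#' @param score Optional detection confidence in \[0, 1\].
#' @param source `"truth"` or `"prediction"`.
#' @return Tibble of boxes.
#' @export
detection_boxes <- function(xmin, ymin, xmax, ymax, score = NA_real_,
                            source = "prediction") {
  b <- tibble::tibble(xmin = as.numeric(xmin), ymin = as.numeric(ymin),
                      xmax = as.numeric(xmax), ymax = as.numeric(ymax),
                      score = as.numeric(score), source = source)
  if (any(b$xmax <= b$xmin) || any(b$ymax <= b$ymin)) {
    stop("degenerate box: xmax must exceed xmin and ymax must exceed ymin",
         call. = FALSE)
  }
  sc <- b$score[!is.na(b$score)]
  if (any(sc < 0 | sc > 1)) stop("scores must lie in [0, 1]", call. = FALSE)
  b
}

#' Intersection over union of two axis-aligned boxes
#'
#' @param a,b Single-row box tibbles (or lists with xmin/ymin/xmax/ymax).
#' @return IoU in \[0, 1\]; 0 for disjoint boxes.
#' @examples
#' box_iou(detection_boxes(0, 0, 2, 2), detection_boxes(1, 1, 3, 3)) # 1/7
#' @export
box_iou <- function(a, b) {
  if (a$xmax <= a$xmin || a$ymax <= a$ymin ||
      b$xmax <= b$xmin || b$ymax <= b$ymin) {
    stop("degenerate box", call. = FALSE)
  }
  iw <- min(a$xmax, b$xmax) - max(a$xmin, b$xmin)
  ih <- min(a$ymax, b$ymax) - max(a$ymin, b$ymin)
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a$xmax - a$xmin) * (a$ymax - a$ymin) +
    (b$xmax - b$xmin) * (b$ymax - b$ymin) - inter
  inter / union
}

# Vectorised IoU of one box against a box tibble.
iou_vec <- function(box, boxes) {
  if (nrow(boxes) == 0) return(numeric(0))
  iw <- pmin(box$xmax, boxes$xmax) - pmax(box$xmin, boxes$xmin)
  ih <- pmin(box$ymax, boxes$ymax) - pmax(box$ymin, boxes$ymin)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  union <- (box$xmax - box$xmin) * (box$ymax - box$ymin) +
    (boxes$xmax - boxes$xmin) * (boxes$ymax - boxes$ymin) - inter
  inter / union
}

#' Greedy matching of predictions to ground truth
#'
#' Predictions are visited in decreasing score order (ties broken by `xmin`,
#' then `ymin`); each claims the unmatched truth box with the highest IoU,
#' provided that IoU exceeds the threshold. A prediction whose best
#' unmatched IoU does not exceed the threshold is a false positive — this
#' includes second and later detections of an already-claimed truth (the
#' duplicate-detection rule). Truths never claimed are false negatives.
#'
#' @param preds Prediction boxes (scored for AP use).
#' @param truths Truth boxes.
#' @param iou_threshold TP requires IoU strictly above this (default 0.5).
#' @return List with `tp`, `fp`, `fn`, `matches` (tibble `pred`, `truth`,
#'   `iou`) and `pred_tp`, a logical flag per prediction in the visiting
#'   order of `preds` as given.
#' @export
match_detections <- function(preds, truths, iou_threshold = 0.5) {
  np <- nrow(preds); nt <- nrow(truths)
  if (np == 0) {
    return(list(tp = 0L, fp = 0L, fn = nt,
                matches = tibble::tibble(pred = integer(0), truth = integer(0),
                                         iou = numeric(0)),
                pred_tp = logical(0)))
  }
  ord <- order(-ifelse(is.na(preds$score), 0, preds$score), preds$xmin, preds$ymin)
  matched_truth <- logical(nt)
  pred_tp <- logical(np)
  matches <- list()
  for (i in ord) {
    if (nt == 0) break
    ious <- iou_vec(preds[i, ], truths)
    ious[matched_truth] <- -Inf
    j <- which.max(ious)
    if (length(j) && ious[j] > iou_threshold) {
      matched_truth[j] <- TRUE
      pred_tp[i] <- TRUE
      matches[[length(matches) + 1L]] <- tibble::tibble(pred = i, truth = j,
                                                        iou = ious[j])
    }
  }
  tp <- sum(pred_tp)
  list(tp = tp, fp = np - tp, fn = nt - tp,
       matches = dplyr::bind_rows(matches,
         tibble::tibble(pred = integer(0), truth = integer(0), iou = numeric(0))),
       pred_tp = pred_tp)
}

#' Detection metrics: precision, recall, F1 and average precision
#'
#' Matching runs per image (grouping by an `image_id` column when present)
#' and the counts are pooled. Precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2TP/(2TP+FP+FN) (the harmonic mean of precision and recall). AP is
#' the area under the precision-recall curve swept over the score threshold,
#' with the all-point precision-envelope interpolation, at the single IoU
#' threshold.
#'
#' @param preds Prediction boxes (optionally with `image_id`).
#' @param truths Truth boxes (optionally with `image_id`).
#' @param iou_threshold IoU threshold (TP strictly above it).
#' @return One-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`,
#'   `average_precision`, `iou_threshold`. With no truths and no predictions
#'   all ratio metrics are `NA` (undefined), not 0.
#' @export
evaluate_detections <- function(preds, truths, iou_threshold = 0.5) {
  if (!"image_id" %in% names(preds)) preds$image_id <- 1L
  if (!"image_id" %in% names(truths)) truths$image_id <- 1L
  ids <- union(unique(preds$image_id), unique(truths$image_id))
  tp <- fp <- fn <- 0L
  flagged <- list()
  for (id in ids) {
    p <- preds[preds$image_id == id, ]
    t <- truths[truths$image_id == id, ]
    m <- match_detections(p, t, iou_threshold)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    if (nrow(p) > 0) flagged[[length(flagged) + 1L]] <-
      tibble::tibble(score = p$score, tp = m$pred_tp)
  }
  n_truth <- tp + fn
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (n_truth > 0) tp / n_truth else NA_real_
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  ap <- if (n_truth > 0 && length(flagged) > 0) {
    sc <- dplyr::bind_rows(flagged)
    sc <- sc[order(-ifelse(is.na(sc$score), 0, sc$score)), ]
    ctp <- cumsum(sc$tp); cfp <- cumsum(!sc$tp)
    rec <- ctp / n_truth
    prec <- ctp / (ctp + cfp)
    # precision envelope (non-increasing from the right), all-point AP
    prec_env <- rev(cummax(rev(prec)))
    sum(diff(c(0, rec)) * prec_env)
  } else if (n_truth > 0) 0 else NA_real_
  tibble::tibble(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, average_precision = ap,
                 iou_threshold = iou_threshold)
}

#' Classical blob-detector baseline for mound detection
#'
#' Thresholds the image at a background quantile plus a contrast margin,
#' labels connected components, keeps components whose equivalent diameter
#' falls in the expected mound diameter range, and scores each by its
#' normalised mean excess brightness.
#'
#' @param pixels Image matrix (intensities on a 0–1 scale) or an
#'   `ortho_image`.
#' @param gsd Ground sample distance, m/px (taken from the `ortho_image` if
#'   one is given).
#' @param diameter_range Expected object diameter range in metres (default
#'   0.15–0.50, the molehill prior).
#' @param contrast_threshold Margin above the background quantile (default
#'   0.1).
#' @param background_quantile Quantile of the image treated as background
#'   level (default 0.5, the median of a mostly-background scene).
#' @return Scored prediction boxes (possibly empty).
#' @export
baseline_blob_detector <- function(pixels, gsd = NULL,
                                   diameter_range = c(0.15, 0.50),
                                   contrast_threshold = 0.1,
                                   background_quantile = 0.5) {
  if (inherits(pixels, "ortho_image")) {
    if (is.null(gsd)) gsd <- pixels$gsd
    pixels <- pixels$pixels
  }
  stopifnot(is.matrix(pixels), !is.null(gsd), gsd > 0)
  thr <- stats::quantile(pixels, background_quantile, names = FALSE) + contrast_threshold
  mask <- pixels > thr
  if (!any(mask)) {
    return(detection_boxes(numeric(0), numeric(0), numeric(0), numeric(0)))
  }
  lab <- EBImage::bwlabel(mask * 1L)
  nlab <- max(lab)
  d_px <- diameter_range / gsd
  out <- list()
  for (k in seq_len(nlab)) {
    idx <- which(lab == k, arr.ind = TRUE)
    area <- nrow(idx)
    eq_diam <- 2 * sqrt(area / pi)
    if (eq_diam < d_px[1] || eq_diam > d_px[2]) next
    excess <- mean(pixels[idx]) - thr
    out[[length(out) + 1L]] <- tibble::tibble(
      xmin = min(idx[, "col"]) - 1, ymin = min(idx[, "row"]) - 1,
      xmax = max(idx[, "col"]), ymax = max(idx[, "row"]),
      score = excess)
  }
  if (length(out) == 0) {
    return(detection_boxes(numeric(0), numeric(0), numeric(0), numeric(0)))
  }
  b <- dplyr::bind_rows(out)
  b$score <- b$score / max(b$score) # normalise to (0, 1]
  detection_boxes(b$xmin, b$ymin, b$xmax, b$ymax, score = b$score)
}
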