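# Independent oracles used across tests. These deliberately avoid the code
# paths they check: brute-force scans, pixel counting, exhaustive
# enumeration.

# IoU by pixel counting on a fine grid (exact when box edges align with the
# grid step).
iou_pixel_oracle <- function(a, b, step = 0.05) {
  x0 <- min(a$xmin, b$xmin); x1 <- max(a$xmax, b$xmax)
  y0 <- min(a$ymin, b$ymin); y1 <- max(a$ymax, b$ymax)
  xs <- seq(x0 + step / 2, x1, by = step)
  ys <- seq(y0 + step / 2, y1, by = step)
  g <- expand.grid(x = xs, y = ys)
  in_a <- g$x > a$xmin & g$x < a$xmax & g$y > a$ymin & g$y < a$ymax
  in_b <- g$x > b$xmin & g$x < b$xmax & g$y > b$ymin & g$y < b$ymax
  sum(in_a & in_b) / sum(in_a | in_b)
}

# AUC by brute-force O(n^2) pair scan with half-credit ties.
auc_pair_oracle <- function(score, label) {
  pos <- score[label == 1]; neg <- score[label == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  a <- tot / (length(pos) * length(neg))
  max(a, 1 - a)
}

# Maximum-cardinality assignment of predictions to truths with IoU > thr,
# by exhaustive enumeration over injective mappings (instances <= 6 boxes).
optimal_match_oracle <- function(preds, truths, thr = 0.5) {
  np <- nrow(preds); nt <- nrow(truths)
  if (np == 0 || nt == 0) return(0L)
  iou <- matrix(0, np, nt)
  for (i in seq_len(np)) for (j in seq_len(nt)) {
    iou[i, j] <- box_iou(preds[i, ], truths[j, ])
  }
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (np - i + 1) <= best) return()
    if (i > np) { best <<- max(best, count); return() }
    for (j in seq_len(nt)) {
      if (!used[j] && iou[i, j] > thr) {
        used[j] <- TRUE
        recurse(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
    recurse(i + 1L, used, count)
  }
  recurse(1L, logical(nt), 0L)
  best
}

# Wald z and p for a 2x2 comparison of proportions on the logit scale, with
# SE = sqrt(1/a + 1/b + 1/c + 1/d).
wald_2x2_oracle <- function(x1, n1, x2, n2) {
  lo <- function(x, n) log(x / (n - x))
  se <- sqrt(1 / x1 + 1 / (n1 - x1) + 1 / x2 + 1 / (n2 - x2))
  z <- (lo(x2, n2) - lo(x1, n1)) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Presence/absence of plots by direct pairwise distance scan.
score_plots_oracle <- function(plots, mounds) {
  sapply(seq_len(nrow(plots)), function(i) {
    if (nrow(mounds) == 0) return(0L)
    d <- sqrt((mounds$x - plots$x[i])^2 + (mounds$y - plots$y[i])^2)
    as.integer(any(d <= plots$radius_m[i]))
  })
}

# Isopleth area by an independent fine-grid accumulation (cell size fixed by
# the caller); same definition, separately coded.
isopleth_area_oracle <- function(points, kernel_radius, mass_fraction, cell) {
  pad <- kernel_radius + 2 * cell
  xs <- seq(min(points$x) - pad, max(points$x) + pad, by = cell)
  ys <- seq(min(points$y) - pad, max(points$y) + pad, by = cell)
  dens <- matrix(0, length(ys), length(xs))
  for (k in seq_len(nrow(points))) {
    d2 <- outer((ys + cell / 2 - points$y[k])^2,
                (xs + cell / 2 - points$x[k])^2, `+`)
    inside <- d2 <= kernel_radius^2
    dens <- dens + inside / sum(inside)
  }
  v <- sort(as.vector(dens), decreasing = TRUE)
  cum <- cumsum(v)
  thr <- v[which(cum >= mass_fraction * sum(v) - 1e-12)[1]]
  sum(dens >= thr & dens > 0) * cell^2
}

# A small scenario configuration for pipeline mechanics tests (reduced
# problem size; generator rates as in the preset).
small_scenario <- function(master_seed = 1L) {
  scenario_config(
    name = "small",
    master_seed = master_seed,
    landscape = landscape_rectangle(500, 400),
    avoidance = avoidance_params(burrow_count = 40, colony_nuclei = 2,
                                 colony_spread = 80, seed = master_seed),
    zones = zone_config(colony_kernel_radius = 40),
    years = tibble::tibble(year = 2019L, burrow_count = 40L,
                           n_burrow_plots = 40L, n_colony_plots = 25L,
                           n_control_plots = 30L),
    image = image_spec(),
    effort = effort_config(),
    mole_kernel_radii = c(5, 10),
    render_window_m = 25
  )
}
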