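# Binomial zone model, AUC, and unadjusted (LSD-style) pairwise contrasts.
#
# The omnibus model is a logistic regression of plot presence on the zone
# factor (reference level BURROW). With one categorical predictor the model
# is saturated, so fitted per-zone probabilities equal the empirical
# proportions — a property the tests assert to 1e-8. "LSD" pairwise
# comparisons are unadjusted Wald contrasts of zone log-odds; when a zone is
# completely separated (all 0 or all 1) its Wald standard errors are
# unusable, and contrasts involving it fall back to Fisher's exact test on
# the 2x2 table.

zone_levels_present <- function(plots) {
  lv <- c("BURROW", "COLONY", "CONTROL")
  c(lv[lv %in% unique(plots$zone)], setdiff(unique(plots$zone), lv))
}

#' Fit the binomial zone model
#'
#' @param plots Scored plots for a single year (columns `zone`, `presence`).
#' @return A `zone_fit` object: the glm fit plus per-zone counts and fitted
#'   probabilities, the AUC of the fitted scores (rank statistic with
#'   half-credit for ties), and per-zone separation flags.
#' @examples
#' plots <- tibble::tibble(
#'   zone = rep(c("BURROW", "COLONY", "CONTROL"), c(200, 100, 150)),
#'   presence = c(rep(c(1L, 0L), c(12, 188)), rep(c(1L, 0L), c(18, 82)),
#'                rep(c(1L, 0L), c(66, 84))))
#' fit <- fit_zone_model(plots)
#' glance(fit)
#' @export
fit_zone_model <- function(plots) {
  stopifnot(all(c("zone", "presence") %in% names(plots)))
  if (anyNA(plots$presence)) stop("plots must be scored", call. = FALSE)
  if (length(unique(plots$zone)) < 2) stop("need at least 2 zones", call. = FALSE)
  if (all(plots$presence == 0) || all(plots$presence == 1)) {
    stop("need both presences and absences overall", call. = FALSE)
  }
  lv <- zone_levels_present(plots)
  dat <- tibble::tibble(zone = factor(plots$zone, levels = lv),
                        presence = as.integer(plots$presence))
  model <- stats::glm(presence ~ zone, family = stats::binomial(), data = dat,
                      control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  counts <- dat |>
    dplyr::group_by(.data$zone) |>
    dplyr::summarise(n = dplyr::n(), present = sum(.data$presence),
                     proportion = mean(.data$presence), .groups = "drop") |>
    dplyr::mutate(separated = .data$present == 0 | .data$present == .data$n)
  counts$fitted_probability <- unname(stats::predict(
    model, tibble::tibble(zone = counts$zone), type = "response"))
  structure(
    list(model = model, by_zone = counts, zone_levels = lv,
         auc = auc_rank(stats::fitted(model), dat$presence),
         n = nrow(dat)),
    class = "zone_fit"
  )
}

#' Rank-statistic AUC with half-credit ties
#'
#' Mann-Whitney form: the probability that a random presence plot scores
#' above a random absence plot, ties counted half. Oriented so the returned
#' value is at least 0.5.
#'
#' @param score Numeric scores (e.g. fitted probabilities).
#' @param label 0/1 outcomes.
#' @return AUC in \[0.5, 1\].
#' @export
auc_rank <- function(score, label) {
  label <- as.integer(label)
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  a <- (sum(r[label == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  max(a, 1 - a)
}

#' @export
print.zone_fit <- function(x, ...) {
  cat(sprintf("<zone_fit> n = %d, AUC = %.4f\n", x$n, x$auc))
  print(x$by_zone)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the zone-model coefficients
#'
#' @param x A `zone_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate` (log-odds), `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy zone_fit
#' @export
tidy.zone_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' One-row summary of a zone-model fit
#'
#' @param x A `zone_fit`.
#' @param ... Unused.
#' @return Tibble with `n`, `auc`, `deviance`, `null.deviance`,
#'   `df.residual`, `any_separation`.
#' @method glance zone_fit
#' @export
glance.zone_fit <- function(x, ...) {
  tibble::tibble(n = x$n, auc = x$auc,
                 deviance = stats::deviance(x$model),
                 null.deviance = x$model$null.deviance,
                 df.residual = stats::df.residual(x$model),
                 any_separation = any(x$by_zone$separated))
}

#' Unadjusted pairwise zone contrasts (LSD style)
#'
#' For each pair of zones, the Wald z statistic on the difference of zone
#' log-odds (covariance from the model fit) and its two-sided p value, with
#' no multiplicity adjustment. Contrasts involving a completely separated
#' zone instead report Fisher's exact test on the 2x2 presence table
#' (`method = "fisher"`), since the Wald standard error is unbounded there.
#'
#' @param fit A `zone_fit`.
#' @return Tibble with `zone_a`, `zone_b`, `diff_log_odds` (b minus a), `z`,
#'   `p_value`, `method`.
#' @export
pairwise_lsd <- function(fit) {
  stopifnot(inherits(fit, "zone_fit"))
  lv <- fit$zone_levels
  V <- stats::vcov(fit$model)
  beta <- stats::coef(fit$model)
  # zone log-odds eta_z = c_z' beta with c = intercept + dummy
  cvec <- function(z) {
    v <- numeric(length(beta)); names(v) <- names(beta)
    v["(Intercept)"] <- 1
    term <- paste0("zone", z)
    if (term %in% names(v)) v[term] <- 1
    v
  }
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  by_zone <- fit$by_zone
  purrr::map_dfr(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    sep <- by_zone$separated[match(c(a, b), as.character(by_zone$zone))]
    if (any(sep)) {
      ca <- by_zone[match(a, as.character(by_zone$zone)), ]
      cb <- by_zone[match(b, as.character(by_zone$zone)), ]
      tab <- matrix(c(ca$present, ca$n - ca$present,
                      cb$present, cb$n - cb$present), nrow = 2, byrow = TRUE)
      p <- stats::fisher.test(tab)$p.value
      tibble::tibble(zone_a = a, zone_b = b, diff_log_odds = NA_real_,
                     z = NA_real_, p_value = p, method = "fisher")
    } else {
      cc <- cvec(b) - cvec(a)
      est <- sum(cc * beta)
      se <- sqrt(drop(t(cc) %*% V %*% cc))
      z <- est / se
      tibble::tibble(zone_a = a, zone_b = b, diff_log_odds = est, z = z,
                     p_value = 2 * stats::pnorm(-abs(z)), method = "wald")
    }
  })
}
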