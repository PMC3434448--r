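#' Regress tree serial order on stereotaxic coordinates
#'
#' Ordinary least squares of the dendrogram serial order (rank 1 at the top
#' of the tree) on the signed LR, PA and IS centroid coordinates:
#' `order = a + b*LR + c*PA + d*IS`. A spatially faithful tree shows a
#' strong, negative PA coefficient (anterior areas at the top) and a
#' near-zero LR coefficient (homotopic left-right pairs interleave). LR
#' enters signed here; rectification belongs to the compactness analyses.
#'
#' @param order A `leaf_order` (or data frame with `rank` and `label`).
#' @param atlas An `area_atlas` containing every ordered label.
#' @return A `layout_regression`: list with `coefficients` (a, b, c, d),
#'   `t_stats`, `p_values`, `f_statistic`, `df` (regression, residual),
#'   `r_squared`, `data` and the underlying `lm` fit.
#' @export
fit_order_on_coordinates <- function(order, atlas) {
  idx <- match(order$label, atlas$label)
  if (anyNA(idx)) {
    stop("labels absent from atlas: ",
         paste(order$label[is.na(idx)], collapse = ", "))
  }
  n <- nrow(order)
  if (n < 5) stop("need at least 5 areas for a 3-predictor regression")
  df <- data.frame(order = order$rank, lr = atlas$lr[idx],
                   pa = atlas$pa[idx], is = atlas$is[idx],
                   label = order$label, stringsAsFactors = FALSE)
  if (qr(cbind(1, df$lr, df$pa, df$is))$rank < 4) {
    stop("coordinate columns are collinear; regression is rank deficient")
  }
  fit <- stats::lm(order ~ lr + pa + is, data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(
    coefficients = stats::setNames(co[, 1], c("a", "b", "c", "d")),
    t_stats = stats::setNames(co[, 3], c("a", "b", "c", "d")),
    p_values = stats::setNames(co[, 4], c("a", "b", "c", "d")),
    f_statistic = unname(sm$fstatistic[1]),
    df = c(regression = 3, residual = n - 4),
    r_squared = sm$r.squared,
    data = df, fit = fit),
    class = "layout_regression")
}

#' @export
print.layout_regression <- function(x, ...) {
  k <- x$coefficients
  cat(sprintf(
    "tree order = %.2f %+.3f*LR %+.3f*PA %+.3f*IS\n", k[1], k[2], k[3], k[4]))
  cat(sprintf("F(%d,%d) = %.1f, R^2 = %.3f\n",
              x$df["regression"], x$df["residual"], x$f_statistic,
              x$r_squared))
  invisible(x)
}

#' Predicted tree order from a fitted layout regression
#'
#' Fitted serial order per area, for the observed-versus-predicted scatter.
#' With `atlas` supplied, predictions are computed for its coordinates;
#' otherwise the training areas are used.
#'
#' @param result A `layout_regression`.
#' @param atlas Optional `area_atlas` of areas to predict for.
#' @return Data frame with `label`, `observed` (NA for new areas) and
#'   `predicted`.
#' @export
predicted_order <- function(result, atlas = NULL) {
  stopifnot(inherits(result, "layout_regression"))
  if (is.null(atlas)) {
    data.frame(label = result$data$label, observed = result$data$order,
               predicted = unname(stats::fitted(result$fit)),
               stringsAsFactors = FALSE)
  } else {
    nd <- data.frame(lr = atlas$lr, pa = atlas$pa, is = atlas$is)
    obs <- result$data$order[match(atlas$label, result$data$label)]
    data.frame(label = atlas$label, observed = obs,
               predicted = unname(stats::predict(result$fit, newdata = nd)),
               stringsAsFactors = FALSE)
  }
}
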