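#' Discard initial volumes of a raw series
#'
#' Scanner equilibration contaminates the first few volumes, which are
#' dropped before any analysis (e.g. 203 -> 200 with `k = 3`).
#'
#' @param series Numeric vector.
#' @param k Number of leading values to discard.
#' @return The last `length(series) - k` values, in order.
#' @export
trim_initial_volumes <- function(series, k = 3) {
  stopifnot(is.numeric(series), length(k) == 1, k >= 0)
  if (length(series) <= k) {
    stop("series length (", length(series),
         ") must exceed the number of trimmed volumes (", k, ")")
  }
  if (k == 0) return(series)
  series[-seq_len(k)]
}

#' Filter voxels by coefficient of variation
#'
#' Voxels near large vessels or outside the brain show a high coefficient of
#' variation (sd/mean); only voxels with CV at or below `max_cv` are kept.
#' Voxels with non-positive mean, for which the CV is undefined, are flagged
#' and excluded with an explicit reason rather than silently dropped.
#'
#' @param voxels Numeric matrix, one voxel series per row.
#' @param max_cv Maximum allowed coefficient of variation (default 0.05,
#'   i.e. 5 percent).
#' @return List with `retained` (the surviving rows) and `report` (one row
#'   per input voxel: `mean`, `sd`, `cv`, `retained`, `reason`).
#' @export
cv_filter <- function(voxels, max_cv = 0.05) {
  if (is.vector(voxels)) voxels <- matrix(voxels, nrow = 1)
  stopifnot(is.matrix(voxels), max_cv >= 0)
  mu <- rowMeans(voxels)
  sdv <- apply(voxels, 1, stats::sd)
  cv <- ifelse(mu > 0, sdv / mu, NA_real_)
  keep <- !is.na(cv) & cv <= max_cv
  reason <- rep("", nrow(voxels))
  reason[is.na(cv)] <- "non-positive mean"
  reason[!is.na(cv) & cv > max_cv] <- "cv above threshold"
  report <- data.frame(
    voxel = if (is.null(rownames(voxels))) seq_len(nrow(voxels))
            else rownames(voxels),
    mean = mu, sd = sdv, cv = cv, retained = keep, reason = reason,
    stringsAsFactors = FALSE, row.names = NULL)
  list(retained = voxels[keep, , drop = FALSE], report = report)
}

#' Prewhiten one raw series to ARIMA innovations
#'
#' Fits an ARIMA(p, d, q) model (default (15, 1, 1)) and returns its
#' residuals -- the "innovations", which are stationary and practically
#' non-autocorrelated when the model is adequate -- together with whiteness
#' diagnostics. When a fit fails, progressively simpler fallback orders are
#' tried; if all fail the result is flagged `converged = FALSE` so callers
#' can exclude the voxel.
#'
#' @param series Numeric raw series.
#' @param order ARIMA order `c(p, d, q)`.
#' @param method Estimation criterion passed to [stats::arima()]:
#'   `"CSS"` (conditional sum of squares, the default -- fast and adequate
#'   for long AR orders), `"CSS-ML"` or `"ML"` (full maximum likelihood).
#'   The criterion used is recorded in the result.
#' @param lb_lags Lags for the Ljung-Box whiteness test on the innovations.
#' @param lb_adjust_df If `TRUE`, subtract `p + q` fitted parameters from
#'   the Ljung-Box degrees of freedom (off by default).
#' @param fallback_orders Orders tried, in turn, when the requested fit
#'   fails.
#' @return An `innovation_series`: list with `values` (residuals, the first
#'   `d` dropped), `model_order`, `method`, `ljung_box_q`, `ljung_box_p`,
#'   `durbin_watson`, `converged`, `fallback_used`.
#' @export
fit_innovations <- function(series, order = c(15, 1, 1), method = "CSS",
                            lb_lags = 20, lb_adjust_df = FALSE,
                            fallback_orders = list(c(5, 1, 1), c(1, 1, 1))) {
  stopifnot(is.numeric(series), length(order) == 3)
  if (stats::sd(series) == 0) stop("constant series: zero variance")
  floor_n <- sum(order) + 1
  if (length(series) < floor_n) {
    stop("series too short (", length(series), ") for order (",
         paste(order, collapse = ","), "); need at least ", floor_n)
  }
  orders <- c(list(as.numeric(order)), fallback_orders)
  fit <- NULL
  used <- NULL
  for (o in orders) {
    cand <- tryCatch(
      suppressWarnings(stats::arima(series, order = o, method = method)),
      error = function(e) NULL)
    if (!is.null(cand) && all(is.finite(stats::residuals(cand))) &&
        cand$code == 0) {
      fit <- cand
      used <- o
      break
    }
    if (is.null(fit) && !is.null(cand) &&
        all(is.finite(stats::residuals(cand)))) {
      # keep a non-converged but finite fit in case every order fails
      fit <- cand
      used <- o
    }
  }
  if (is.null(fit)) {
    return(structure(list(values = NULL, model_order = as.numeric(order),
                          method = method, ljung_box_q = NA_real_,
                          ljung_box_p = NA_real_, durbin_watson = NA_real_,
                          converged = FALSE, fallback_used = NA),
                     class = "innovation_series"))
  }
  d <- used[2]
  res <- as.numeric(stats::residuals(fit))
  if (d > 0) res <- res[-seq_len(d)]
  fitdf <- if (lb_adjust_df) used[1] + used[3] else 0
  lb <- ljung_box_q(res, n_lags = lb_lags, fitdf = fitdf)
  structure(list(values = res, model_order = used, method = method,
                 ljung_box_q = lb$statistic, ljung_box_p = lb$p_value,
                 durbin_watson = durbin_watson(res),
                 converged = fit$code == 0,
                 fallback_used = !identical(used, as.numeric(order))),
            class = "innovation_series")
}

#' @export
print.innovation_series <- function(x, ...) {
  cat(sprintf(
    "innovation_series: n=%d, order=(%s), %s, LB p=%.3f, DW=%.2f%s\n",
    length(x$values), paste(x$model_order, collapse = ","), x$method,
    x$ljung_box_p, x$durbin_watson,
    if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Ljung-Box portmanteau test for residual autocorrelation
#'
#' Q = n (n + 2) sum_{k=1..L} rho_k^2 / (n - k), referred to a chi-square
#' with `L - fitdf` degrees of freedom. Small p-values indicate remaining
#' autocorrelation, i.e. incomplete prewhitening.
#'
#' @param residuals Numeric residual series.
#' @param n_lags Number of autocorrelation lags L.
#' @param fitdf Degrees-of-freedom correction for fitted ARMA parameters
#'   (0 by default).
#' @return List with `statistic` (Q) and `p_value`.
#' @export
ljung_box_q <- function(residuals, n_lags = 20, fitdf = 0) {
  stopifnot(is.numeric(residuals))
  if (n_lags >= length(residuals)) {
    stop("n_lags (", n_lags, ") must be smaller than the series length (",
         length(residuals), ")")
  }
  bt <- stats::Box.test(residuals, lag = n_lags, type = "Ljung-Box",
                        fitdf = fitdf)
  list(statistic = unname(bt$statistic), p_value = unname(bt$p.value))
}

#' Durbin-Watson statistic of a residual series
#'
#' `sum(diff(e)^2) / sum(e^2)`; values near 2 indicate no first-order
#' autocorrelation, values near 0 strong positive autocorrelation (a red
#' flag for spurious correlation between raw series).
#'
#' @param residuals Numeric residual series, length >= 2.
#' @return The statistic, in `[0, 4]`.
#' @export
durbin_watson <- function(residuals) {
  stopifnot(is.numeric(residuals), length(residuals) >= 2)
  denom <- sum(residuals^2)
  if (denom == 0) stop("zero variance: all residuals are zero")
  sum(diff(residuals)^2) / denom
}

#' Prewhiten every voxel of a raw dataset
#'
#' Applies, per voxel: initial-volume trimming, the coefficient-of-variation
#' filter (on the trimmed series, since that is the series analyzed), and
#' ARIMA prewhitening with whiteness diagnostics. Voxels failing the CV
#' filter or all ARIMA fits are excluded and logged in the diagnostics
#' table.
#'
#' @param dataset A `raw_dataset`.
#' @param order ARIMA order, default `c(15, 1, 1)`.
#' @param trim Leading volumes to discard (default 3).
#' @param max_cv CV threshold (default 0.05).
#' @param method Estimation criterion, see [fit_innovations()].
#' @param lb_lags Ljung-Box lags.
#' @return An `innovations_dataset`: `subjects` (area label -> innovations
#'   matrix, voxels x time), `atlas`, `diagnostics` (one row per input
#'   voxel: retention, model order, Ljung-Box p, Durbin-Watson), and the
#'   settings used.
#' @export
prewhiten_dataset <- function(dataset, order = c(15, 1, 1), trim = 3,
                              max_cv = 0.05, method = "CSS", lb_lags = 20) {
  stopifnot(inherits(dataset, "raw_dataset"))
  diag_rows <- list()
  out <- lapply(names(dataset$subjects), function(s) {
    areas <- dataset$subjects[[s]]
    res <- lapply(names(areas), function(a) {
      m <- areas[[a]]
      trimmed <- t(apply(m, 1, trim_initial_volumes, k = trim))
      cvf <- cv_filter(trimmed, max_cv = max_cv)
      kept <- cvf$retained
      fits <- vector("list", nrow(kept))
      ok <- logical(nrow(kept))
      for (i in seq_len(nrow(kept))) {
        fits[[i]] <- fit_innovations(kept[i, ], order = order,
                                     method = method, lb_lags = lb_lags)
        ok[i] <- fits[[i]]$converged
      }
      rep_df <- cvf$report
      rep_df$subject <- s
      rep_df$area <- a
      rep_df$converged <- NA
      rep_df$lb_p <- NA_real_
      rep_df$dw <- NA_real_
      rep_df$order <- NA_character_
      ki <- which(rep_df$retained)
      for (j in seq_along(ki)) {
        f <- fits[[j]]
        rep_df$converged[ki[j]] <- f$converged
        rep_df$lb_p[ki[j]] <- f$ljung_box_p
        rep_df$dw[ki[j]] <- f$durbin_watson
        rep_df$order[ki[j]] <- paste(f$model_order, collapse = ",")
        if (!f$converged) rep_df$reason[ki[j]] <- "arima did not converge"
      }
      rep_df$retained[ki[!ok]] <- FALSE
      diag_rows[[length(diag_rows) + 1]] <<- rep_df
      if (!any(ok)) return(matrix(numeric(0), 0, 0))
      do.call(rbind, lapply(fits[ok], function(f) f$values))
    })
    names(res) <- names(areas)
    res
  })
  names(out) <- names(dataset$subjects)
  diagnostics <- do.call(rbind, diag_rows)
  rownames(diagnostics) <- NULL
  structure(list(subjects = out, atlas = dataset$atlas,
                 diagnostics = diagnostics,
                 settings = list(order = order, trim = trim,
                                 max_cv = max_cv, method = method,
                                 lb_lags = lb_lags)),
            class = "innovations_dataset")
}

#' @export
print.innovations_dataset <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "innovations_dataset: %d subjects, %d areas; %d/%d voxels retained\n",
    length(x$subjects), nrow(x$atlas), sum(d$retained), nrow(d)))
  invisible(x)
}
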