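#' Random k-fold partition
#'
#' Uniformly random fold assignment with fold sizes differing by at most
#' one, reproducible by seed.
#'
#' @param n Number of observations.
#' @param k Number of folds (default 6).
#' @param seed Optional integer seed.
#' @return Integer vector of fold labels in `1:k`, length `n`.
#' @export
kfold_split <- function(n, k = 6, seed = NULL) {
  stopifnot(k >= 2)
  if (k > n) stop("more folds than observations")
  if (!is.null(seed)) set.seed(seed)
  rep_len(seq_len(k), n)[sample.int(n)]
}

#' k-fold cross-validation of the external-drift kriging model
#'
#' For each fold the full model (variogram parameters by REML and drift
#' coefficients by GLS) is refit on the remaining folds and the held-out
#' locations are predicted; held-out points contribute to neither the
#' variogram nor the drift estimates of their own prediction. Aggregated
#' diagnostics are the Pearson correlation between predicted and measured
#' values and the least-squares calibration line of predicted on measured
#' (slope < 1 indicates smoothing shrinkage: high values underestimated,
#' low values overestimated).
#'
#' @inheritParams edkrige
#' @param k Number of folds, default 6.
#' @param seed Seed for the fold assignment.
#' @param ... Passed to [edkrige()] (e.g. `n_starts`).
#' @return Object of class `"edk_cv"`: data frame `table` (per-sample fold,
#'   measured, predicted, se), `pearson_r`, `calib_slope`,
#'   `calib_intercept`, `k`, `seed`.
#' @export
edk_cv <- function(data, canal, drift = drift_spec("quadratic"), k = 6,
                   seed = NULL, gamma = 0.5, ...) {
  n <- nrow(data)
  fold <- kfold_split(n, k, seed)
  pred <- se <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- tryCatch(
      edkrige(data[!test, , drop = FALSE], canal, drift = drift,
              gamma = gamma, ...),
      error = function(e) stop(sprintf("fold %d fit failed: %s", f,
                                       conditionMessage(e)), call. = FALSE))
    pr <- predict(fit, data[test, c("x", "y")])
    pred[test] <- pr$mean
    se[test] <- pr$se
  }
  r <- stats::cor(pred, data$z)
  cal <- stats::lm(pred ~ data$z)
  structure(list(
    table = data.frame(fold = fold, x = data$x, y = data$y,
                       measured = data$z, predicted = pred, se = se),
    pearson_r = r,
    calib_slope = unname(stats::coef(cal)[2]),
    calib_intercept = unname(stats::coef(cal)[1]),
    k = k, seed = seed), class = "edk_cv")
}

#' @export
print.edk_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (n = %d)\n", x$k, nrow(x$table)))
  cat(sprintf("  Pearson r (predicted vs measured): %.3f\n", x$pearson_r))
  cat(sprintf("  Calibration line: predicted = %.3f + %.3f * measured\n",
              x$calib_intercept, x$calib_slope))
  invisible(x)
}

#' @export
plot.edk_cv <- function(x, ...) {
  graphics::plot(x$table$measured, x$table$predicted, pch = 16, cex = 0.5,
                 xlab = "measured log10 Hg", ylab = "predicted log10 Hg", ...)
  graphics::abline(0, 1, col = "red")
  graphics::abline(x$calib_intercept, x$calib_slope, col = "blue")
  invisible(x)
}
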