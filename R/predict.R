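#' Kriging prediction at arbitrary locations
#'
#' Universal (external-drift) kriging predictor
#' \deqn{\hat p(s_0) = x_0^T \hat\beta + c_0^T \Sigma^{-1} (y - X\hat\beta),}
#' with the prediction variance of the *signal* `Z(s0) = x0' beta + B(s0)`
#' (excluding the nugget),
#' \deqn{\sigma^2 - c_0^T \Sigma^{-1} c_0 + d^T (X^T \Sigma^{-1} X)^{-1} d,
#'  \quad d = x_0 - X^T \Sigma^{-1} c_0,}
#' which includes the drift-estimation uncertainty. `type = "response"`
#' adds the nugget `tau2` for prediction of a new noisy observation.
#'
#' @param object An [edkrige()] fit.
#' @param newdata Data frame (or two-column matrix) of target coordinates
#'   `x`, `y` in meters.
#' @param type `"signal"` (default) or `"response"`.
#' @param se.fit Return standard errors (default `TRUE`).
#' @param ... Unused.
#' @return Data frame with columns `x`, `y`, `mean` (log10 mg/kg) and, if
#'   requested, `se` (log10 mg/kg).
#' @export
predict.edk <- function(object, newdata, type = c("signal", "response"),
                        se.fit = TRUE, ...) {
  type <- match.arg(type)
  if (is.matrix(newdata)) newdata <- data.frame(x = newdata[, 1], y = newdata[, 2])
  stopifnot(all(c("x", "y") %in% names(newdata)))
  if (!all(is.finite(newdata$x)) || !all(is.finite(newdata$y))) {
    stop("target coordinates must be finite")
  }
  vp <- object$vp
  ld0 <- log_distance(distance_to_polyline(newdata$x, newdata$y, object$canal),
                      object$dist_floor)
  X0 <- build_drift_design(ld0, object$drift)
  mu <- drop(X0 %*% object$beta)

  m <- nrow(X0)
  if (vp$sigma2 == 0 || object$cache$degenerate) {
    mean_pred <- mu
    if (!se.fit) return(data.frame(x = newdata$x, y = newdata$y, mean = mean_pred))
    if (object$cache$degenerate) {
      se <- rep(0, m)
    } else {
      quad <- colSums(t(X0) * (object$cache$Minv %*% t(X0)))
      se <- sqrt(pmax(quad + if (type == "response") vp$tau2 else 0, 0))
    }
    return(data.frame(x = newdata$x, y = newdata$y, mean = mean_pred, se = se))
  }

  # cross-covariances between targets and observations (n x m)
  DX <- outer(object$data$x, newdata$x, "-")
  DY <- outer(object$data$y, newdata$y, "-")
  c0 <- stable_exponential_cov(sqrt(DX * DX + DY * DY), vp)
  mean_pred <- mu + drop(crossprod(c0, object$cache$w))
  if (!se.fit) return(data.frame(x = newdata$x, y = newdata$y, mean = mean_pred))

  A <- backsolve(object$cache$cS, c0, transpose = TRUE)   # L^{-1} c0
  c0Sic0 <- colSums(A^2)
  d <- t(X0) - crossprod(object$cache$Xw, A)              # x0 - X' Sigma^{-1} c0
  quad <- colSums(d * (object$cache$Minv %*% d))
  v <- vp$sigma2 - c0Sic0 + quad
  if (type == "response") v <- v + vp$tau2
  data.frame(x = newdata$x, y = newdata$y, mean = mean_pred,
             se = sqrt(pmax(v, 0)))
}

#' Kriging prediction on a regular grid
#'
#' Evaluates [predict.edk()] at the centers of a regular grid covering a
#' bounding box. Cells are ordered row-major: `y` varies slowest (from
#' `ymin` upward), `x` fastest.
#'
#' @param object An [edkrige()] fit.
#' @param bbox Numeric `c(xmin, xmax, ymin, ymax)` in meters.
#' @param cell_size Cell edge length in meters, > 0.
#' @param max_cells Guard against accidental huge rasters (default 200000).
#' @param type Passed to [predict.edk()].
#' @return Data frame `x`, `y`, `mean`, `se` with attributes `nx`, `ny`,
#'   `cell_size`.
#' @export
predict_grid <- function(object, bbox, cell_size, max_cells = 200000,
                         type = "signal") {
  stopifnot(length(bbox) == 4, cell_size > 0)
  xmin <- bbox[1]; xmax <- bbox[2]; ymin <- bbox[3]; ymax <- bbox[4]
  if (xmax <= xmin || ymax <= ymin) stop("degenerate bounding box")
  xs <- seq(xmin + cell_size / 2, xmax, by = cell_size)
  ys <- seq(ymin + cell_size / 2, ymax, by = cell_size)
  if (length(xs) * length(ys) > max_cells) {
    stop(sprintf("grid would have %d cells (cap %d); increase cell_size",
                 length(xs) * length(ys), max_cells))
  }
  centers <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  out <- predict.edk(object, centers, type = type)
  attr(out, "nx") <- length(xs)
  attr(out, "ny") <- length(ys)
  attr(out, "cell_size") <- cell_size
  out
}

#' Write a prediction grid as CSV
#'
#' @param grid Result of [predict_grid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  utils::write.csv(
    data.frame(x = grid$x, y = grid$y,
               mean_log10 = grid$mean, se_log10 = grid$se),
    path, row.names = FALSE)
  invisible(path)
}
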