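#' Variogram parameters of the stable exponential model
#'
#' Container for the spatial covariance parameters of the stable exponential
#' (powered exponential) family: partial sill `sigma2` (variance of the
#' spatially correlated field, (log10 mg/kg)^2), nugget `tau2` (variance of
#' the iid measurement error), range `alpha` (meters) and shape exponent
#' `gamma` (dimensionless, in (0, 2]; `gamma = 1` is the exponential model,
#' `gamma = 0.5` the non-differentiable default used throughout).
#'
#' @param sigma2 Partial sill, >= 0.
#' @param tau2 Nugget, >= 0.
#' @param alpha Range in meters, > 0.
#' @param gamma Shape exponent in (0, 2], default 0.5.
#' @return Object of class `"variogram_params"`.
#' @examples
#' variogram_params(0.32, 0.003, 46.67)
#' @export
variogram_params <- function(sigma2, tau2, alpha, gamma = 0.5) {
  stopifnot(is.finite(sigma2), sigma2 >= 0,
            is.finite(tau2), tau2 >= 0,
            is.finite(alpha), alpha > 0,
            is.finite(gamma), gamma > 0, gamma <= 2)
  structure(list(sigma2 = sigma2, tau2 = tau2, alpha = alpha, gamma = gamma),
            class = "variogram_params")
}

#' @export
print.variogram_params <- function(x, ...) {
  cat(sprintf(
    "Stable exponential variogram: sill %.4g, nugget %.4g, range %.4g m, shape %.3g\n",
    x$sigma2, x$tau2, x$alpha, x$gamma))
  invisible(x)
}

#' Stable exponential covariance function
#'
#' `C(r) = sigma2 * exp(-(r/alpha)^gamma)`. The nugget is *not* included:
#' this is the covariance of the smooth (auto-correlated) field component.
#'
#' @param r Separation distances in meters, >= 0.
#' @param vp A [variogram_params()].
#' @return Covariances, same length as `r`.
#' @export
stable_exponential_cov <- function(r, vp) {
  stopifnot(inherits(vp, "variogram_params"))
  if (any(r < 0)) stop("separation distances must be non-negative")
  vp$sigma2 * exp(-(r / vp$alpha)^vp$gamma)
}

#' Theoretical semivariogram of the stable exponential model
#'
#' `gamma(h) = tau2 + sigma2 * (1 - exp(-(h/alpha)^gamma))` for `h > 0`.
#'
#' @inheritParams stable_exponential_cov
#' @param h Lags in meters.
#' @return Semivariances.
#' @export
theoretical_semivariance <- function(h, vp) {
  stopifnot(inherits(vp, "variogram_params"))
  vp$tau2 + vp$sigma2 * (1 - exp(-(h / vp$alpha)^vp$gamma))
}

# full covariance matrix of observations: sigma2 * C + tau2 * I
cov_matrix_obs <- function(D, vp) {
  S <- stable_exponential_cov(D, vp)
  diag(S) <- vp$sigma2 + vp$tau2
  S
}

#' Matheron (method-of-moments) empirical semivariogram
#'
#' The classical estimator: for each lag bin, half the average squared
#' difference over all point pairs whose separation falls in the bin,
#' `gammahat(h) = sum (z_i - z_j)^2 / (2 N(h))`.
#'
#' @param x,y Sample coordinates (meters).
#' @param z Sample values (typically log10 mg/kg).
#' @param bins Either a single number of equal-width bins (default 15,
#'   spanning (0, max pairwise distance / 2]) or a numeric vector of
#'   ordered bin edges.
#' @param max_lag Upper lag limit when `bins` is a count; defaults to half
#'   the maximum pairwise distance.
#' @return Object of class `"empirical_variogram"`: data frame with columns
#'   `lag` (bin centers, meters), `gamma` (semivariance), `n_pairs`. Empty
#'   bins carry `NA` semivariance.
#' @export
matheron_variogram <- function(x, y, z, bins = 15, max_lag = NULL) {
  stopifnot(length(x) == length(y), length(x) == length(z))
  if (length(x) < 2) stop("need at least 2 samples")
  D <- as.matrix(stats::dist(cbind(x, y)))
  dv <- D[lower.tri(D)]
  if (!length(dv)) stop("no point pairs available")
  G <- outer(z, z, "-")^2
  gv <- G[lower.tri(G)]
  if (length(bins) == 1L) {
    if (is.null(max_lag)) max_lag <- max(dv) / 2
    edges <- seq(0, max_lag, length.out = bins + 1L)
  } else {
    edges <- sort(bins)
  }
  idx <- findInterval(dv, edges, rightmost.closed = TRUE, left.open = TRUE)
  nb <- length(edges) - 1L
  keep <- idx >= 1L & idx <= nb
  idx <- idx[keep]; gv2 <- gv[keep]
  n_pairs <- tabulate(idx, nbins = nb)
  ssq <- vapply(seq_len(nb), function(b) sum(gv2[idx == b]), numeric(1))
  sv <- ifelse(n_pairs > 0, ssq / (2 * n_pairs), NA_real_)
  out <- data.frame(lag = (edges[-1] + edges[-length(edges)]) / 2,
                    gamma = sv, n_pairs = n_pairs)
  class(out) <- c("empirical_variogram", "data.frame")
  out
}

#' @export
plot.empirical_variogram <- function(x, vp = NULL, ...) {
  graphics::plot(x$lag, x$gamma, xlab = "lag (m)",
                 ylab = "semivariance", pch = 16, ...)
  if (!is.null(vp)) {
    h <- seq(min(x$lag) / 2, max(x$lag), length.out = 200)
    graphics::lines(h, theoretical_semivariance(h, vp), col = "red")
  }
  invisible(x)
}
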