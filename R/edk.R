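#' Fit an external-drift kriging model by restricted maximum likelihood
#'
#' Fits the spatial linear model
#' \deqn{Y(s_i) = x(s_i)^T \beta + B(s_i) + \epsilon_i,}
#' where the drift covariates `x(s)` are functions of the base-10 log
#' distance to the canal ([build_drift_design()]), `B` is a stationary
#' Gaussian random field with stable exponential covariance
#' `sigma2 * exp(-(r/alpha)^gamma)` and `epsilon` is iid measurement noise
#' with variance `tau2` (the nugget). The variance parameters
#' `(sigma2, tau2, alpha)` are estimated by Gaussian REML with the shape
#' exponent `gamma` held fixed (default 0.5); `beta` is the generalized
#' least squares estimate at the optimum.
#'
#' Optimization runs on `log(tau2/sigma2)` and `log(alpha)` with the
#' overall scale `sigma2` profiled out analytically. Several starting
#' points are derived from the Matheron variogram of the OLS drift
#' residuals; the best converged start wins.
#'
#' @param data Data frame with planar coordinates `x`, `y` (meters) and the
#'   response `z` (log10 mg/kg soil mercury).
#' @param canal A [polyline()]: the contamination source geometry.
#' @param drift A [drift_spec()]; default quadratic (the drift used for all
#'   downstream prediction).
#' @param gamma Fixed shape exponent of the stable exponential covariance.
#' @param vp Optional [variogram_params()]. When supplied, REML is skipped
#'   and `beta` is the GLS estimate under these fixed parameters (with
#'   `sigma2 = tau2 = 0` this reduces exactly to the OLS drift fit).
#' @param dist_floor Clamp for [log_distance()], meters.
#' @param n_starts Number of multi-start initializations (default 5).
#'   Optimization stops early once two starts agree closely.
#' @param control Passed to [stats::optim()] (Nelder-Mead); sensible
#'   defaults are merged in.
#' @param jitter Amount (meters) by which exactly duplicated locations are
#'   perturbed, with a warning, so the covariance stays non-singular.
#' @return Object of class `"edk"`. Key components: `beta` (named drift
#'   coefficients), `vp` (fitted [variogram_params()]), `converged`,
#'   `neg2reml` (the REML criterion at the optimum), `data`, and cached
#'   factorizations used by [predict.edk()].
#' @seealso [predict.edk()], [predict_grid()], [edk_cv()], [qq_residuals()]
#' @examples
#' canal <- polyline(c(0, 1000), c(0, 0))
#' set.seed(1)
#' cfg <- sim_config(n_soil = 120, seed = 1)
#' soil <- simulate_soil(cfg)
#' fit <- edkrige(data.frame(x = soil$x, y = soil$y, z = log10(soil$hg_mgkg)),
#'                sim_canal(cfg), n_starts = 2)
#' fit
#' @export
edkrige <- function(data, canal, drift = drift_spec("quadratic"),
                    gamma = 0.5, vp = NULL, dist_floor = 1,
                    n_starts = 5, control = list(), jitter = 1e-3) {
  stopifnot(inherits(canal, "polyline"), inherits(drift, "drift_spec"))
  stopifnot(all(c("x", "y", "z") %in% names(data)))
  xy <- cbind(data$x, data$y)
  y <- as.numeric(data$z)
  if (!all(is.finite(xy)) || !all(is.finite(y))) stop("non-finite inputs")
  if (is.null(vp) && stats::sd(y) == 0) {
    stop("response is constant; variogram parameters cannot be estimated")
  }

  dup <- duplicated(xy)
  if (any(dup)) {
    warning(sprintf("%d duplicated locations jittered by %g m", sum(dup), jitter))
    xy[dup, ] <- xy[dup, ] + stats::runif(2 * sum(dup), -jitter, jitter)
  }

  ld <- log_distance(distance_to_polyline(xy[, 1], xy[, 2], canal), dist_floor)
  X <- build_drift_design(ld, drift)
  n <- nrow(X); p <- ncol(X)
  if (n < p + 3) stop("too few samples for the drift and variogram parameters")
  D <- as.matrix(stats::dist(xy))

  if (is.null(vp)) {
    est <- edk_reml_optimize(D, X, y, gamma, n_starts, control)
    vp <- est$vp
    converged <- est$converged
    neg2reml <- est$value
    ev <- est$ev
  } else {
    stopifnot(inherits(vp, "variogram_params"))
    if (vp$gamma != gamma) gamma <- vp$gamma
    converged <- TRUE
    neg2reml <- NA_real_
    ev <- NULL
  }

  cache <- edk_build_cache(D, X, y, vp)
  structure(list(beta = cache$beta, vp = vp, drift = drift, gamma = gamma,
                 converged = converged, neg2reml = neg2reml,
                 data = data.frame(x = xy[, 1], y = xy[, 2], z = y),
                 logdist = ld, X = X, canal = canal, dist_floor = dist_floor,
                 n = n, p = p, cache = cache, emp_variogram = ev,
                 call = match.call()),
            class = "edk")
}

# profiled REML criterion in (log nu, log alpha); nu = tau2/sigma2.
# returns the -2*(restricted log-likelihood) up to an additive constant.
edk_profile_criterion <- function(par, D, X, y, gamma) {
  nu <- exp(par[1]); alpha <- exp(par[2])
  if (!is.finite(nu) || !is.finite(alpha) || alpha <= 0) return(1e10)
  n <- nrow(X); p <- ncol(X)
  V <- exp(-(D / alpha)^gamma)
  diag(V) <- 1 + nu
  cV <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cV)) return(1e10)
  Xw <- backsolve(cV, X, transpose = TRUE)
  yw <- backsolve(cV, y, transpose = TRUE)
  M <- crossprod(Xw)
  cM <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(cM)) return(1e10)
  b <- backsolve(cM, backsolve(cM, crossprod(Xw, yw), transpose = TRUE))
  rss <- sum(yw^2) - sum(crossprod(Xw, yw) * b)
  if (rss <= 0) return(1e10)
  (n - p) * log(rss / (n - p)) + 2 * sum(log(diag(cV))) + 2 * sum(log(diag(cM)))
}

edk_reml_optimize <- function(D, X, y, gamma, n_starts, control) {
  n <- nrow(X); p <- ncol(X)
  # starts from the empirical variogram of the OLS drift residuals
  b0 <- stats::lm.fit(X, y)$coefficients
  r0 <- y - X %*% b0
  xy_d <- D  # distances already available
  ev <- local({
    dv <- xy_d[lower.tri(xy_d)]
    max_lag <- max(dv) / 2
    edges <- seq(0, max_lag, length.out = 16L)
    idx <- findInterval(dv, edges, rightmost.closed = TRUE, left.open = TRUE)
    gv <- outer(as.numeric(r0), as.numeric(r0), "-")^2
    gv <- gv[lower.tri(gv)]
    keep <- idx >= 1 & idx <= 15
    npairs <- tabulate(idx[keep], 15)
    sv <- vapply(1:15, function(b) sum(gv[keep][idx[keep] == b]), numeric(1))
    data.frame(lag = (edges[-1] + edges[-16]) / 2,
               gamma = ifelse(npairs > 0, sv / (2 * npairs), NA),
               n_pairs = npairs)
  })
  class(ev) <- c("empirical_variogram", "data.frame")
  ok <- is.finite(ev$gamma)
  sill0 <- if (any(ok)) mean(ev$gamma[ok][max(1, sum(ok) - 4):sum(ok)]) else stats::var(r0)
  nug0 <- if (any(ok)) max(min(ev$gamma[ok]) / 2, sill0 * 1e-3) else sill0 * 0.05
  psill0 <- max(sill0 - nug0, sill0 * 0.1)
  # lag where the variogram reaches ~63% of the partial sill
  a0 <- {
    tgt <- nug0 + (1 - exp(-1)) * psill0
    hit <- which(ok & ev$gamma >= tgt)
    if (length(hit)) ev$lag[hit[1]] else max(ev$lag) / 4
  }
  nu0 <- min(max(nug0 / psill0, 1e-4), 10)
  starts <- list(c(log(nu0), log(a0)),
                 c(log(nu0 / 10), log(a0 / 3)),
                 c(log(nu0 * 10), log(a0 * 3)),
                 c(log(nu0), log(a0 * 3)),
                 c(log(nu0 / 30), log(a0)))
  starts <- starts[seq_len(max(1, min(n_starts, length(starts))))]
  ctl <- utils::modifyList(list(maxit = 500, reltol = 1e-9), control)

  best <- NULL
  vals <- c()
  for (s in starts) {
    o <- stats::optim(s, edk_profile_criterion, D = D, X = X, y = y,
                      gamma = gamma, method = "Nelder-Mead", control = ctl)
    vals <- c(vals, o$value)
    if (is.null(best) || o$value < best$value) best <- o
    # early exit: two starts agree on the optimum
    if (length(vals) >= 2 && diff(range(sort(vals)[1:2])) < 1e-6) break
  }
  if (!is.finite(best$value) || best$value >= 1e10) {
    stop("REML optimization failed to find a usable optimum")
  }
  nu <- exp(best$par[1]); alpha <- exp(best$par[2])
  # recover the profiled scale
  V <- exp(-(D / alpha)^gamma); diag(V) <- 1 + nu
  cV <- chol(V)
  Xw <- backsolve(cV, X, transpose = TRUE)
  yw <- backsolve(cV, y, transpose = TRUE)
  M <- crossprod(Xw)
  b <- solve(M, crossprod(Xw, yw))
  rss <- sum(yw^2) - sum(crossprod(Xw, yw) * b)
  sigma2 <- rss / (n - p)
  list(vp = variogram_params(sigma2, nu * sigma2, alpha, gamma),
       converged = best$convergence == 0, value = best$value, ev = ev)
}

# factorizations shared by beta, predictions and residuals
edk_build_cache <- function(D, X, y, vp) {
  n <- nrow(X)
  total <- vp$sigma2 + vp$tau2
  if (total == 0) {
    Sigma <- diag(n)  # degenerate: GLS collapses to OLS
  } else {
    Sigma <- cov_matrix_obs(D, vp)
  }
  cS <- chol(Sigma)
  Xw <- backsolve(cS, X, transpose = TRUE)
  yw <- backsolve(cS, y, transpose = TRUE)
  M <- crossprod(Xw)
  Minv <- solve(M)
  beta <- drop(Minv %*% crossprod(Xw, yw))
  names(beta) <- colnames(X)
  resid <- y - drop(X %*% beta)
  # w = Sigma^{-1} (y - X beta)
  w <- backsolve(cS, backsolve(cS, resid, transpose = TRUE))
  list(beta = beta, cS = cS, Xw = Xw, Minv = Minv, w = w, resid = resid,
       degenerate = total == 0)
}

#' @export
print.edk <- function(x, ...) {
  cat(sprintf("External-drift kriging model (%s drift, gamma = %.3g, n = %d)\n",
              x$drift$kind, x$gamma, x$n))
  cat("Drift coefficients:\n")
  print(round(x$beta, 4))
  print(x$vp)
  if (!x$converged) cat("WARNING: REML optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.edk <- function(object, ...) object$beta

#' @export
logLik.edk <- function(object, ...) {
  val <- if (is.na(object$neg2reml)) NA_real_ else {
    -0.5 * (object$neg2reml + (object$n - object$p) * (log(2 * pi) + 1))
  }
  structure(val, df = object$p + 3, class = "logLik")
}

#' @export
summary.edk <- function(object, ...) {
  se <- sqrt(diag(object$cache$Minv))
  z <- object$beta / se
  tab <- data.frame(term = names(object$beta), estimate = object$beta,
                    se = se,
                    ci_low = object$beta - 1.96 * se,
                    ci_high = object$beta + 1.96 * se,
                    p_value = 2 * stats::pnorm(-abs(z)), row.names = NULL)
  structure(list(coefficients = tab, vp = object$vp, n = object$n,
                 drift = object$drift, converged = object$converged,
                 neg2reml = object$neg2reml),
            class = "summary.edk")
}

#' @export
print.summary.edk <- function(x, digits = 4, ...) {
  cat(sprintf("External-drift kriging model (%s drift, n = %d)\n",
              x$drift$kind, x$n))
  print(x$coefficients, digits = digits)
  print(x$vp)
  if (is.finite(x$neg2reml)) {
    cat(sprintf("-2 * restricted log-likelihood (profiled, up to const): %.3f\n",
                x$neg2reml))
  }
  invisible(x)
}

#' REML criterion at arbitrary variance parameters
#'
#' Evaluates minus twice the restricted log-likelihood (up to an additive
#' constant that does not depend on the parameters) of the external-drift
#' spatial model at user-supplied `(sigma2, tau2, alpha)`. Useful for
#' checking that the fitted parameters are at least as good as alternatives.
#'
#' @inheritParams edkrige
#' @param sigma2,tau2,alpha Variance parameters at which to evaluate.
#' @return Scalar: `-2 * restricted log-likelihood + const`.
#' @export
reml_neg2loglik <- function(data, canal, sigma2, tau2, alpha,
                            drift = drift_spec("quadratic"), gamma = 0.5,
                            dist_floor = 1) {
  ld <- log_distance(distance_to_polyline(data$x, data$y, canal), dist_floor)
  X <- build_drift_design(ld, drift)
  y <- as.numeric(data$z)
  n <- nrow(X); p <- ncol(X)
  D <- as.matrix(stats::dist(cbind(data$x, data$y)))
  vp <- variogram_params(sigma2, tau2, alpha, gamma)
  Sigma <- cov_matrix_obs(D, vp)
  cS <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(cS)) return(Inf)
  Xw <- backsolve(cS, X, transpose = TRUE)
  yw <- backsolve(cS, y, transpose = TRUE)
  M <- crossprod(Xw)
  b <- solve(M, crossprod(Xw, yw))
  rss <- sum(yw^2) - sum(crossprod(Xw, yw) * b)
  2 * sum(log(diag(cS))) + determinant(M)$modulus[1] + rss
}

#' Residuals of an external-drift kriging model
#'
#' @param object An `"edk"` fit.
#' @param type `"whitened"` (default): drift residuals decorrelated by the
#'   Cholesky factor of the fitted covariance, approximately iid standard
#'   normal under the model. `"response"`: raw drift residuals `y - X beta`.
#' @param ... Unused.
#' @export
residuals.edk <- function(object, type = c("whitened", "response"), ...) {
  type <- match.arg(type)
  if (type == "response") return(object$cache$resid)
  drop(backsolve(object$cache$cS, object$cache$resid, transpose = TRUE))
}

#' Q-Q pairs of whitened kriging residuals
#'
#' Whitened residuals sorted against standard-normal quantiles; under a
#' correctly specified Gaussian model the pairs lie near the identity line.
#'
#' @param object An `"edk"` fit.
#' @return Data frame with columns `theoretical`, `observed`.
#' @export
qq_residuals <- function(object) {
  stopifnot(inherits(object, "edk"))
  w <- residuals.edk(object, "whitened")
  data.frame(theoretical = stats::qnorm(stats::ppoints(length(w))),
             observed = sort(w))
}

#' Diagnostic plots for an external-drift kriging fit
#'
#' Left: Matheron variogram of the OLS drift residuals with the fitted
#' stable exponential semivariogram. Right: normal Q-Q plot of whitened
#' residuals.
#'
#' @param x An `"edk"` fit.
#' @param ... Passed to the variogram panel.
#' @export
plot.edk <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  ev <- x$emp_variogram
  if (is.null(ev)) {
    ev <- matheron_variogram(x$data$x, x$data$y, x$cache$resid)
  }
  plot(ev, vp = x$vp, main = "Variogram", ...)
  qq <- qq_residuals(x)
  graphics::plot(qq$theoretical, qq$observed, pch = 16, cex = 0.6,
                 xlab = "theoretical quantiles", ylab = "observed quantiles",
                 main = "Whitened residuals")
  graphics::abline(0, 1, col = "red")
  invisible(x)
}

#' Simulate from a fitted external-drift kriging model
#'
#' Draws responses at the training locations from the fitted model
#' (drift + Gaussian field + nugget noise) by exact Cholesky simulation.
#'
#' @param object An `"edk"` fit.
#' @param nsim Number of replicates.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return An `n x nsim` matrix.
#' @export
simulate.edk <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  mu <- drop(object$X %*% object$beta)
  C <- stable_exponential_cov(as.matrix(stats::dist(cbind(object$data$x, object$data$y))),
                              object$vp)
  L <- chol(C + diag(1e-10 * max(object$vp$sigma2, 1), n))
  field <- t(L) %*% matrix(stats::rnorm(n * nsim), n, nsim)
  noise <- matrix(stats::rnorm(n * nsim, sd = sqrt(object$vp$tau2)), n, nsim)
  mu + field + noise
}
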