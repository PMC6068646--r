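#' Drift specification
#'
#' The external drift is a regression of log10 soil mercury on the base-10
#' log distance to the canal. Four candidate mean functions are supported:
#' \describe{
#'   \item{linear}{intercept + logdist}
#'   \item{quadratic}{intercept + logdist + logdist^2}
#'   \item{broken_stick}{intercept + logdist + hinge `max(0, logdist - breakpoint)`}
#'   \item{inverse}{intercept + logdist + `(1 + logdist)^-1`}
#' }
#'
#' @param kind One of `"linear"`, `"quadratic"`, `"broken_stick"`, `"inverse"`.
#' @param breakpoint Hinge location on the log10-distance scale
#'   (broken_stick only), default 2 (i.e. 100 m).
#' @return Object of class `"drift_spec"`.
#' @export
drift_spec <- function(kind = c("linear", "quadratic", "broken_stick", "inverse"),
                       breakpoint = 2) {
  kind <- match.arg(kind)
  stopifnot(is.finite(breakpoint))
  structure(list(kind = kind, breakpoint = breakpoint), class = "drift_spec")
}

drift_kinds <- c("linear", "quadratic", "broken_stick", "inverse")

#' @export
print.drift_spec <- function(x, ...) {
  cat("Drift:", x$kind,
      if (x$kind == "broken_stick") sprintf("(breakpoint %.3g)", x$breakpoint),
      "\n")
  invisible(x)
}

#' Build the drift design matrix
#'
#' @param logdist Vector of base-10 log distances ([log_distance()]).
#' @param spec A [drift_spec()].
#' @return An `n x p` design matrix with intercept.
#' @examples
#' build_drift_design(c(1.5, 3), drift_spec("broken_stick"))
#' @export
build_drift_design <- function(logdist, spec) {
  stopifnot(inherits(spec, "drift_spec"), all(is.finite(logdist)))
  d <- as.numeric(logdist)
  X <- switch(spec$kind,
    linear = cbind(1, d),
    quadratic = cbind(1, d, d^2),
    broken_stick = cbind(1, d, pmax(0, d - spec$breakpoint)),
    inverse = {
      if (any(1 + d == 0)) stop("inverse drift undefined where 1 + logdist = 0")
      cbind(1, d, 1 / (1 + d))
    })
  colnames(X) <- switch(spec$kind,
    linear = c("(Intercept)", "logdist"),
    quadratic = c("(Intercept)", "logdist", "logdist2"),
    broken_stick = c("(Intercept)", "logdist", "hinge"),
    inverse = c("(Intercept)", "logdist", "inv1p"))
  X
}

#' Fit one drift model by ordinary least squares
#'
#' Gaussian linear model of the response on the drift design. AIC and BIC
#' use the Gaussian log-likelihood at the maximum-likelihood variance with
#' the parameter count including the error variance (the `stats::AIC`
#' convention).
#'
#' @param y Response vector (log10 mg/kg).
#' @param logdist Base-10 log distances to the canal.
#' @param spec A [drift_spec()].
#' @return Object of class `"drift_fit"`: coefficient table (estimate,
#'   95% CI, p), `aic`, `bic`, `sigma2` (MLE residual variance), `n`, the
#'   underlying `lm` fit, and the `spec`.
#' @export
fit_drift_ols <- function(y, logdist, spec) {
  X <- build_drift_design(logdist, spec)
  if (length(y) <= ncol(X)) stop("need more observations than drift parameters")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient drift design")
  fit <- stats::lm(y ~ X - 1)
  cf <- summary(fit)$coefficients
  rownames(cf) <- colnames(X)
  ci <- cbind(cf[, 1] - stats::qnorm(0.975) * cf[, 2],
              cf[, 1] + stats::qnorm(0.975) * cf[, 2])
  coefficients <- data.frame(term = colnames(X), estimate = cf[, 1],
                             ci_low = ci[, 1], ci_high = ci[, 2],
                             p_value = cf[, 4], row.names = NULL)
  structure(list(spec = spec, coefficients = coefficients,
                 sigma2 = mean(stats::residuals(fit)^2),
                 aic = stats::AIC(fit), bic = stats::BIC(fit),
                 logLik = as.numeric(stats::logLik(fit)),
                 n = length(y), lm = fit),
            class = "drift_fit")
}

#' @export
print.drift_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Drift model '%s' (n = %d): AIC %.1f, BIC %.1f\n",
              x$spec$kind, x$n, x$aic, x$bic))
  print(x$coefficients, digits = digits)
  invisible(x)
}

#' @export
coef.drift_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Fit and compare the four candidate drift models
#'
#' @inheritParams fit_drift_ols
#' @param breakpoint Breakpoint for the broken-stick candidate.
#' @return Object of class `"drift_table"`: list of [fit_drift_ols()] fits
#'   (one per candidate) plus a comparison data frame.
#' @export
drift_table <- function(y, logdist, breakpoint = 2) {
  fits <- lapply(drift_kinds, function(k)
    fit_drift_ols(y, logdist, drift_spec(k, breakpoint)))
  names(fits) <- drift_kinds
  comparison <- data.frame(
    model = drift_kinds,
    k = vapply(fits, function(f) nrow(f$coefficients) + 1L, integer(1)),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    row.names = NULL)
  structure(list(fits = fits, comparison = comparison), class = "drift_table")
}

#' @export
print.drift_table <- function(x, ...) {
  cat("Drift model comparison (AIC selects:",
      select_drift(x$fits)$kind, ")\n")
  print(x$comparison, digits = 6)
  invisible(x)
}

#' Select the drift with minimal AIC
#'
#' Ties are broken by fewer parameters, then by the fixed candidate order
#' linear, quadratic, broken_stick, inverse.
#'
#' @param fits A list of `"drift_fit"` objects (or a `"drift_table"`).
#' @return The winning [drift_spec()].
#' @export
select_drift <- function(fits) {
  if (inherits(fits, "drift_table")) fits <- fits$fits
  if (!length(fits)) stop("no drift fits to select from")
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  k <- vapply(fits, function(f) nrow(f$coefficients), numeric(1))
  ord <- vapply(fits, function(f) match(f$spec$kind, drift_kinds), numeric(1))
  best <- order(aic, k, ord)[1]
  fits[[best]]$spec
}
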