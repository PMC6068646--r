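#' Attach kriging prediction uncertainty to exposure records
#'
#' Populates `exposure_se` from kriging standard errors, the error
#' magnitude of the Berkson model. Errors are treated as independent
#' across participants (spatial dependence of the prediction error is
#' ignored); co-located participants receive identical SEs.
#'
#' @param records An `"exposure_records"` data frame.
#' @param predictions Either a data frame with columns `id` and `se`
#'   (one row per participant), or a numeric vector of SEs in record
#'   order.
#' @return `records` with `exposure_se` filled in.
#' @export
attach_error_variances <- function(records, predictions) {
  if (is.data.frame(predictions)) {
    stopifnot(all(c("id", "se") %in% names(predictions)))
    idx <- match(records$id, predictions$id)
    if (any(is.na(idx))) {
      stop("missing prediction for record(s): ",
           paste(records$id[is.na(idx)], collapse = ", "))
    }
    se <- predictions$se[idx]
  } else {
    if (length(predictions) != nrow(records)) {
      stop("one standard error per record required")
    }
    se <- as.numeric(predictions)
  }
  if (any(se < 0 | !is.finite(se))) stop("standard errors must be finite and >= 0")
  records$exposure_se <- se
  records
}

# fixed-effect design shared by the naive and Berkson fits
hbm_design <- function(records, det_limit = NULL, interaction = NULL) {
  exposure_kind <- attr(records, "exposure_kind")
  if (is.null(det_limit)) det_limit <- identical(exposure_kind, "measured")
  if (is.null(interaction)) interaction <- identical(exposure_kind, "measured")
  pool <- c("exposure", "age", "mother", "amalgam_sqrt", "seafish_sqrt",
            "seafish_last3d", "smoking", "near_sea", "vegetables",
            "hair_dyeing")
  terms <- intersect(pool, names(records))
  if (det_limit && "below_det_limit" %in% names(records)) {
    terms <- c(terms, "below_det_limit")
  }
  if (interaction && all(c("age", "mother") %in% names(records))) {
    terms <- c(terms, "age:mother")
  }
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fml <- stats::as.formula(paste("~", rhs))
  X <- stats::model.matrix(fml, data = as.data.frame(records))
  list(X = X, y = records$outcome, fam = factor(records$family_id),
       terms = terms)
}

#' Berkson measurement-error outcome regression
#'
#' Treats the kriging-predicted exposure as the center of a Berkson error
#' model: the latent true exposure is `x_true = x_pred + u`,
#' `u ~ N(0, exposure_se^2)` independently across participants, and the
#' outcome follows the family random-intercept regression on `x_true`.
#' Under the linear Gaussian model the latent exposure integrates out in
#' closed form: record `i` contributes residual variance
#' `sigma2_e + beta_soil^2 * se_i^2`. The default scheme is a conservative
#' plug-in correction: variance components are taken from the naive
#' no-error fit, the integrated error term is added to each record's
#' residual variance, and the fixed effects are re-estimated by GLS,
#' iterating on the soil slope until it stabilizes. Because the inflated
#' covariance dominates the naive one, every corrected interval is at
#' least as wide as its naive counterpart, and growing the error SEs can
#' only widen them further. Berkson error in a linear model does not
#' attenuate the slope; it adds uncertainty.
#'
#' `method = "mcmc"` cross-checks the closed-form scheme with a Bayesian
#' sampler on the same marginal model: Gibbs draws for the non-soil fixed
#' effects (conjugate under a vague `N(0, 10^3)` prior) and random-walk
#' Metropolis for the soil slope and the two log standard deviations
#' (half-Gaussian scale-1 priors on the standard deviations).
#'
#' @param records An `"exposure_records"` data frame with `exposure_se`
#'   populated (see [attach_error_variances()] or
#'   [build_exposure_records()] with predicted exposure).
#' @param method `"iterative"` (default) or `"mcmc"`.
#' @param det_limit,interaction Passed to the design construction, as in
#'   [hbm_lmm()].
#' @param max_iter,tol Outer-loop controls for the iterative scheme.
#' @param n_iter,burn,prior_sd_beta,prior_scale_sd MCMC controls.
#' @param seed Optional seed for the sampler.
#' @return Object of class `"berkson_lmm"`: `beta` (corrected Wald or
#'   posterior table), `sigma2_family`, `sigma2_resid`, `naive_ref` (the
#'   matching no-error [hbm_lmm()] fit), `method`, `converged`.
#' @export
berkson_lmm <- function(records, method = c("iterative", "mcmc"),
                        det_limit = NULL, interaction = NULL,
                        max_iter = 100, tol = 1e-10,
                        n_iter = 3000, burn = 1000,
                        prior_sd_beta = sqrt(1000), prior_scale_sd = 1,
                        seed = NULL) {
  method <- match.arg(method)
  if (!"exposure_se" %in% names(records)) stop("exposure_se missing; attach it first")
  naive <- hbm_lmm(records, det_limit = det_limit, interaction = interaction,
                   ci_variances = FALSE)
  des <- hbm_design(records, det_limit, interaction)
  X <- des$X; y <- des$y
  n <- length(y)
  Fsame <- outer(des$fam, des$fam, "==") * 1
  s2u <- records$exposure_se^2
  soil_col <- match("exposure", colnames(X))
  if (is.na(soil_col)) stop("records carry no exposure column")

  if (method == "iterative") {
    res <- berkson_iterative(X, y, Fsame, s2u, soil_col, naive, max_iter, tol)
  } else {
    res <- berkson_mcmc(X, y, Fsame, s2u, soil_col, naive, n_iter, burn,
                        prior_sd_beta, prior_scale_sd, seed)
  }

  structure(c(res, list(naive_ref = naive, method = method,
                        soil_term = "exposure", n = n,
                        n_families = nlevels(des$fam))),
            class = "berkson_lmm")
}

# plug-in variance-inflation scheme: the variance components of the naive
# fit are kept, the integrated Berkson term beta_soil^2 * se_i^2 is added to
# each record's residual variance, and beta is re-estimated by GLS until the
# soil slope stabilizes. Since the inflated covariance dominates the naive
# one in the psd order, every corrected SE is at least the naive SE, and
# inflating the error SEs can never shrink an interval (deliberately
# conservative: the naive variance estimates already contain the error
# noise).
berkson_iterative <- function(X, y, Fsame, s2u, soil_col, naive, max_iter, tol) {
  beta_s <- naive$beta$estimate[naive$beta$term == "exposure"]
  s2f <- naive$sigma2_family[["estimate"]]
  s2e <- max(naive$sigma2_resid[["estimate"]], 1e-10)
  converged <- FALSE
  beta <- NULL; covb <- NULL
  for (it in seq_len(max_iter)) {
    V <- s2f * Fsame
    diag(V) <- diag(V) + s2e + beta_s^2 * s2u
    cS <- chol(V)
    Xw <- backsolve(cS, X, transpose = TRUE)
    yw <- backsolve(cS, y, transpose = TRUE)
    covb <- solve(crossprod(Xw))
    beta <- drop(covb %*% crossprod(Xw, yw))
    new_s <- beta[soil_col]
    if (abs(new_s - beta_s) < tol * max(1, abs(beta_s))) {
      beta_s <- new_s; converged <- TRUE; break
    }
    beta_s <- new_s
  }
  names(beta) <- colnames(X)
  list(beta = wald_table(beta, sqrt(diag(covb))),
       sigma2_family = c(estimate = s2f, ci_low = NA, ci_high = NA),
       sigma2_resid = c(estimate = s2e, ci_low = NA, ci_high = NA),
       converged = converged, iterations = it)
}

berkson_mcmc <- function(X, y, Fsame, s2u, soil_col, naive, n_iter, burn,
                         prior_sd_beta, prior_scale_sd, seed) {
  if (!is.null(seed)) set.seed(seed)
  p <- ncol(X); n <- length(y)
  Xo <- X[, -soil_col, drop = FALSE]
  xs <- X[, soil_col]
  # state: beta (p), log sd_f, log sd_e
  beta <- stats::setNames(naive$beta$estimate[match(colnames(X), naive$beta$term)],
                          colnames(X))
  lsf <- log(sqrt(max(naive$sigma2_family[["estimate"]], 1e-4)))
  lse <- log(sqrt(max(naive$sigma2_resid[["estimate"]], 1e-4)))
  step <- c(naive$beta$se[naive$beta$term == "exposure"], 0.15, 0.1) * 0.8

  make_chol <- function(bs, lsf, lse) {
    V <- exp(2 * lsf) * Fsame
    diag(V) <- diag(V) + exp(2 * lse) + bs^2 * s2u
    chol(V)
  }
  # log joint (marginal in the latent exposure) for the MH block
  log_post <- function(bs, lsf, lse, beta_other) {
    cS <- tryCatch(make_chol(bs, lsf, lse), error = function(e) NULL)
    if (is.null(cS)) return(-Inf)
    mu <- drop(Xo %*% beta_other) + xs * bs
    rw <- backsolve(cS, y - mu, transpose = TRUE)
    ll <- -sum(log(diag(cS))) - 0.5 * sum(rw^2)
    # priors: N(0, prior_sd_beta^2) slope, half-normal sds (+ log-Jacobian)
    ll - 0.5 * (bs / prior_sd_beta)^2 -
      0.5 * (exp(lsf) / prior_scale_sd)^2 + lsf -
      0.5 * (exp(lse) / prior_scale_sd)^2 + lse
  }

  keep <- matrix(NA_real_, n_iter, p + 2,
                 dimnames = list(NULL, c(colnames(X), "sd_family", "sd_resid")))
  acc <- 0
  lp <- log_post(beta[soil_col], lsf, lse, beta[-soil_col])
  for (it in seq_len(n_iter)) {
    # Gibbs: non-soil fixed effects, conjugate given V
    cS <- make_chol(beta[soil_col], lsf, lse)
    yw <- backsolve(cS, y - xs * beta[soil_col], transpose = TRUE)
    Xw <- backsolve(cS, Xo, transpose = TRUE)
    Sinv <- crossprod(Xw) + diag(1 / prior_sd_beta^2, p - 1)
    cP <- chol(Sinv)
    m <- backsolve(cP, backsolve(cP, crossprod(Xw, yw), transpose = TRUE))
    beta[-soil_col] <- drop(m + backsolve(cP, stats::rnorm(p - 1)))
    lp <- log_post(beta[soil_col], lsf, lse, beta[-soil_col])
    # MH: soil slope and log-sds
    prop <- c(beta[soil_col], lsf, lse) + stats::rnorm(3) * step
    lp2 <- log_post(prop[1], prop[2], prop[3], beta[-soil_col])
    if (log(stats::runif(1)) < lp2 - lp) {
      beta[soil_col] <- prop[1]; lsf <- prop[2]; lse <- prop[3]
      lp <- lp2; acc <- acc + 1
    }
    keep[it, ] <- c(beta, exp(lsf), exp(lse))
  }
  keep <- keep[(burn + 1):n_iter, , drop = FALSE]
  est <- colMeans(keep)
  qs <- apply(keep, 2, stats::quantile, probs = c(0.025, 0.975))
  bi <- seq_len(p)
  tail_p <- vapply(bi, function(j) {
    pr <- mean(keep[, j] > 0)
    min(1, 2 * min(pr, 1 - pr))
  }, numeric(1))
  beta_tab <- data.frame(term = colnames(X), estimate = est[bi],
                         se = apply(keep[, bi, drop = FALSE], 2, stats::sd),
                         ci_low = qs[1, bi], ci_high = qs[2, bi],
                         p_value = tail_p, row.names = NULL)
  list(beta = beta_tab,
       sigma2_family = c(estimate = est[p + 1]^2,
                         ci_low = qs[1, p + 1]^2, ci_high = qs[2, p + 1]^2),
       sigma2_resid = c(estimate = est[p + 2]^2,
                        ci_low = qs[1, p + 2]^2, ci_high = qs[2, p + 2]^2),
       converged = acc / n_iter > 0.05, accept_rate = acc / n_iter,
       draws = keep)
}

#' @export
print.berkson_lmm <- function(x, digits = 4, ...) {
  cat(sprintf("Berkson error model (%s scheme): n = %d in %d families\n",
              x$method, x$n, x$n_families))
  print(wald_inference(x), digits = digits)
  s <- x$beta[x$beta$term == x$soil_term, ]
  ns <- x$naive_ref$beta[x$naive_ref$beta$term == x$soil_term, ]
  cat(sprintf("Soil slope: corrected %.4f [%.4f, %.4f] vs naive %.4f [%.4f, %.4f]\n",
              s$estimate, s$ci_low, s$ci_high,
              ns$estimate, ns$ci_low, ns$ci_high))
  if (!x$converged) cat("WARNING: estimation did not converge\n")
  invisible(x)
}

#' @export
coef.berkson_lmm <- function(object, ...) {
  stats::setNames(object$beta$estimate, object$beta$term)
}

#' Comparison report: naive vs Berkson-corrected estimates
#'
#' @param fit A [berkson_lmm()] fit.
#' @return Data frame with naive and corrected estimates, intervals,
#'   p-values and evidence categories per fixed effect.
#' @export
berkson_report <- function(fit) {
  stopifnot(inherits(fit, "berkson_lmm"))
  co <- fit$beta
  na <- fit$naive_ref$beta
  idx <- match(co$term, na$term)
  data.frame(variable = co$term,
             naive_estimate = na$estimate[idx],
             naive_ci_low = na$ci_low[idx], naive_ci_high = na$ci_high[idx],
             corrected_estimate = co$estimate,
             corrected_ci_low = co$ci_low, corrected_ci_high = co$ci_high,
             p_value = co$p_value,
             evidence_category = as.character(categorize_evidence(co$p_value)))
}
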