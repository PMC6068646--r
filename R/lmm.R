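#' Linear mixed model of a log10 HBM outcome with a family random intercept
#'
#' Fits, by REML (through \pkg{lme4}), the Gaussian random-intercept model
#' \deqn{y_{ij} = x_{ij}^T \beta + b_j + e_{ij}, \quad
#'   b_j \sim N(0, \sigma^2_{family}), \; e_{ij} \sim N(0, \sigma^2_e),}
#' where `j` indexes families. Fixed-effect inference is Wald with a
#' Gaussian reference: 95% CI = estimate +/- 1.96 SE, two-sided normal
#' p-values.
#'
#' The fixed-effect set is taken from the columns of `records` (built by
#' [build_exposure_records()]): the soil exposure, the outcome-specific
#' questionnaire covariates, the below-determination-limit indicator for
#' measured exposure, and optionally the age-by-mother interaction.
#'
#' @param records An `"exposure_records"` data frame (or any data frame
#'   with `outcome`, `family_id` and covariate columns).
#' @param covariates Character vector of covariate columns to use; default:
#'   every encoded covariate present in `records` plus `exposure`.
#' @param det_limit Include the determination-limit indicator; default
#'   `TRUE` for measured exposure, `FALSE` for predicted.
#' @param interaction Include the age-by-mother interaction; default
#'   `TRUE` for measured exposure, `FALSE` for predicted.
#' @param ci_variances Compute profile CIs for the variance components
#'   (slower); default `TRUE`.
#' @return Object of class `"hbm_lmm"`: `beta` (Wald table), `sigma2_family`
#'   and `sigma2_resid` (each with CI), `n`, `n_families`, `converged`,
#'   and the underlying `lmerMod` as `fit`.
#' @export
hbm_lmm <- function(records, covariates = NULL, det_limit = NULL,
                    interaction = NULL, ci_variances = TRUE) {
  stopifnot(all(c("outcome", "family_id") %in% names(records)))
  exposure_kind <- attr(records, "exposure_kind")
  if (is.null(det_limit)) det_limit <- identical(exposure_kind, "measured")
  if (is.null(interaction)) interaction <- identical(exposure_kind, "measured")
  if (is.null(covariates)) {
    pool <- c("exposure", "age", "mother", "amalgam_sqrt", "seafish_sqrt",
              "seafish_last3d", "smoking", "near_sea", "vegetables",
              "hair_dyeing")
    covariates <- intersect(pool, names(records))
  }
  if (det_limit && "below_det_limit" %in% names(records)) {
    covariates <- c(covariates, "below_det_limit")
  }
  terms <- covariates
  if (interaction && all(c("age", "mother") %in% names(records))) {
    terms <- c(terms, "age:mother")
  }
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fml <- stats::as.formula(paste("outcome ~", rhs, "+ (1 | family_id)"))
  df <- as.data.frame(records)
  df$family_id <- factor(df$family_id)
  if (nlevels(df$family_id) < 2) stop("need at least 2 families")
  fit <- lme4::lmer(fml, data = df, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  if (any(!is.finite(unlist(stats::vcov(fit))))) stop("singular design")
  converged <- fit@optinfo$conv$opt == 0

  vc <- as.data.frame(lme4::VarCorr(fit))
  s2f <- vc$vcov[vc$grp == "family_id"]
  s2e <- vc$vcov[vc$grp == "Residual"]
  var_ci <- matrix(NA_real_, 2, 2,
                   dimnames = list(c("family", "resid"), c("low", "high")))
  if (ci_variances) {
    ci <- tryCatch(suppressWarnings(
      stats::confint(fit, parm = c(".sig01", ".sigma"), quiet = TRUE)),
      error = function(e) NULL)
    if (!is.null(ci)) var_ci[] <- ci^2
  }

  structure(list(
    beta = wald_table(lme4::fixef(fit), sqrt(diag(as.matrix(stats::vcov(fit))))),
    sigma2_family = c(estimate = s2f, ci_low = var_ci[1, 1], ci_high = var_ci[1, 2]),
    sigma2_resid = c(estimate = s2e, ci_low = var_ci[2, 1], ci_high = var_ci[2, 2]),
    n = nrow(df), n_families = nlevels(df$family_id),
    converged = converged, formula = fml, fit = fit,
    outcome_kind = attr(records, "outcome_kind"),
    exposure_kind = exposure_kind), class = "hbm_lmm")
}

wald_table <- function(est, se) {
  z <- est / se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             ci_low = unname(est - 1.96 * se),
             ci_high = unname(est + 1.96 * se),
             p_value = unname(2 * stats::pnorm(-abs(z))), row.names = NULL)
}

#' Wald inference table of a fitted model
#'
#' Per-coefficient estimate, 95% CI (estimate +/- 1.96 SE) and two-sided
#' p-value from the Gaussian reference, plus the evidence category.
#'
#' @param fit An [hbm_lmm()] or [berkson_lmm()] fit.
#' @return Data frame: `term`, `estimate`, `se`, `ci_low`, `ci_high`,
#'   `p_value`, `evidence`.
#' @export
wald_inference <- function(fit) {
  stopifnot(inherits(fit, c("hbm_lmm", "berkson_lmm")))
  tab <- fit$beta
  tab$evidence <- categorize_evidence(tab$p_value)
  tab
}

evidence_levels <- c("very_strong", "strong", "evidence", "weak",
                     "little_or_none")

#' Categorize a p-value into evidence-for-association classes
#'
#' The Bland communication scale: p < 0.001 very strong evidence,
#' p < 0.01 strong, p < 0.05 evidence, p < 0.1 weak, otherwise little or no
#' evidence. Exact boundary values 0.05 and 0.1 fall to the lower-evidence
#' side.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Ordered factor with levels `very_strong`, `strong`, `evidence`,
#'   `weak`, `little_or_none`.
#' @examples
#' categorize_evidence(c(0.0005, 0.003, 0.03, 0.07, 0.64))
#' @export
categorize_evidence <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  lab <- ifelse(p < 0.001, "very_strong",
         ifelse(p < 0.01, "strong",
         ifelse(p < 0.05, "evidence",
         ifelse(p < 0.1, "weak", "little_or_none"))))
  factor(lab, levels = evidence_levels, ordered = TRUE)
}

#' @export
print.hbm_lmm <- function(x, digits = 4, ...) {
  cat(sprintf("HBM mixed model (%s outcome, %s exposure): n = %d in %d families\n",
              x$outcome_kind %||% "?", x$exposure_kind %||% "?",
              x$n, x$n_families))
  print(wald_inference(x), digits = digits)
  cat(sprintf("Family variance: %.4g   Residual variance: %.4g\n",
              x$sigma2_family[["estimate"]], x$sigma2_resid[["estimate"]]))
  if (!x$converged) cat("WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.hbm_lmm <- function(object, ...) {
  stats::setNames(object$beta$estimate, object$beta$term)
}

#' @export
summary.hbm_lmm <- function(object, ...) object

#' Run the four outcome regressions
#'
#' Builds exposure records and fits the mixed model for every requested
#' combination of outcome (urine, hair) and exposure kind (measured,
#' predicted): the measured-exposure models include the
#' determination-limit indicator and the age-by-mother interaction, the
#' predicted-exposure models omit both.
#'
#' @param participants Participant table (see [build_exposure_records()]).
#' @param soil Topsoil table (LOD-substituted) for measured exposure.
#' @param model An [edkrige()] fit for predicted exposure.
#' @param which Character vector of model names among `"urine_measured"`,
#'   `"urine_predicted"`, `"hair_measured"`, `"hair_predicted"`.
#' @param ... Passed to [hbm_lmm()] (e.g. `ci_variances`, or `det_limit` /
#'   `interaction` to override the defaults).
#' @return Named list of [hbm_lmm()] fits with a `reports` attribute
#'   holding one [model_report()] per fit.
#' @export
run_outcome_models <- function(participants, soil = NULL, model = NULL,
                               which = c("urine_measured", "urine_predicted",
                                         "hair_measured", "hair_predicted"),
                               ...) {
  fits <- list()
  for (w in which) {
    parts <- strsplit(w, "_")[[1]]
    rec <- build_exposure_records(participants, soil = soil, model = model,
                                  outcome_kind = parts[1], exposure = parts[2])
    fits[[w]] <- hbm_lmm(rec, ...)
  }
  attr(fits, "reports") <- lapply(fits, model_report)
  fits
}

#' Report table for one fitted outcome model
#'
#' Mirrors the published layout: one row per fixed effect (coefficient,
#' 95% CI, p-value, evidence category), with the variance components
#' appended as rows.
#'
#' @param fit An [hbm_lmm()] fit.
#' @return Data frame: `variable`, `coefficient`, `ci_low`, `ci_high`,
#'   `p_value`, `evidence_category`.
#' @export
model_report <- function(fit) {
  tab <- wald_inference(fit)
  out <- data.frame(variable = tab$term, coefficient = tab$estimate,
                    ci_low = tab$ci_low, ci_high = tab$ci_high,
                    p_value = tab$p_value,
                    evidence_category = as.character(tab$evidence))
  vr <- data.frame(
    variable = c("sigma2_family", "sigma2_resid"),
    coefficient = c(fit$sigma2_family[["estimate"]], fit$sigma2_resid[["estimate"]]),
    ci_low = c(fit$sigma2_family[["ci_low"]], fit$sigma2_resid[["ci_low"]]),
    ci_high = c(fit$sigma2_family[["ci_high"]], fit$sigma2_resid[["ci_high"]]),
    p_value = NA_real_, evidence_category = NA_character_)
  rbind(out, vr)
}
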