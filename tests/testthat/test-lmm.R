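sim_records <- function(n_fam, per_fam, beta0 = 0.5, fam_sd = 0.2,
                        resid_sd = 0.3, seed = 1) {
  set.seed(seed)
  fam <- rep(seq_len(n_fam), each = per_fam)
  b <- rnorm(n_fam, sd = fam_sd)
  data.frame(outcome = beta0 + b[fam] + rnorm(length(fam), sd = resid_sd),
             family_id = sprintf("F%02d", fam))
}

test_that("balanced two-per-family fit matches the closed-form ANOVA estimator", {
  rec <- sim_records(30, 2, seed = 101)
  fit <- hbm_lmm(rec, ci_variances = FALSE)
  want <- oracle_anova_varcomp(rec$outcome, rec$family_id)
  expect_equal(fit$beta$estimate[1], want$mean, tolerance = 1e-6)
  expect_equal(fit$sigma2_resid[["estimate"]], want$sigma2_e, tolerance = 1e-6)
  expect_equal(fit$sigma2_family[["estimate"]], max(want$sigma2_b, 0),
               tolerance = 1e-6)
})

test_that("zero family variance collapses to the OLS fit", {
  set.seed(102)
  n <- 400
  rec <- data.frame(outcome = 1 + rnorm(n, sd = 0.5),
                    family_id = sprintf("F%03d", rep(1:100, each = 4)),
                    exposure = runif(n, -1, 1))
  rec$outcome <- rec$outcome + 0.3 * rec$exposure
  fit <- hbm_lmm(rec, ci_variances = FALSE)
  ols <- lm(outcome ~ exposure, data = rec)
  expect_lt(fit$sigma2_family[["estimate"]], 1e-3)
  expect_equal(fit$beta$estimate, unname(coef(ols)), tolerance = 1e-4)
})

test_that("Wald inference follows the Gaussian reference", {
  tab <- hgkrige:::wald_table(c(a = 0, b = 1.96 * 2, c = 3), c(1, 2, 1e-8))
  expect_equal(tab$p_value[1], 1)
  expect_equal(tab$p_value[2], 0.05, tolerance = 1e-3)
  expect_lt(tab$p_value[3], 1e-100)
  expect_equal(tab$ci_low, tab$estimate - 1.96 * tab$se)
})

test_that("evidence categories follow the published scale with boundary rules", {
  expect_equal(as.character(categorize_evidence(c(0.0005, 0.003, 0.03, 0.07, 0.64))),
               c("very_strong", "strong", "evidence", "weak", "little_or_none"))
  # boundaries fall to the lower-evidence side
  expect_equal(as.character(categorize_evidence(c(0.001, 0.01, 0.05, 0.1))),
               c("strong", "evidence", "weak", "little_or_none"))
  expect_true(is.ordered(categorize_evidence(0.5)))
  expect_error(categorize_evidence(1.2), "0, 1")
})

test_that("fixed effects are invariant to family relabeling", {
  rec <- sim_records(20, 3, seed = 103)
  rec$exposure <- runif(nrow(rec))
  fit1 <- hbm_lmm(rec, ci_variances = FALSE)
  rec2 <- rec
  rec2$family_id <- factor(rec$family_id,
                           labels = sample(sprintf("G%02d", 1:20)))
  fit2 <- hbm_lmm(rec2, ci_variances = FALSE)
  expect_equal(fit2$beta$estimate, fit1$beta$estimate, tolerance = 1e-8)
})

test_that("REML optimum beats random variance-parameter points", {
  rec <- sim_records(25, 3, seed = 104)
  fit <- hbm_lmm(rec, ci_variances = FALSE)
  dev <- lme4::lmer(outcome ~ 1 + (1 | family_id), data = rec,
                    devFunOnly = TRUE, REML = TRUE)
  th_hat <- lme4::getME(fit$fit, "theta")
  at_fit <- dev(th_hat)
  set.seed(1)
  for (i in 1:20) expect_gte(dev(runif(1, 0, 5)), at_fit - 1e-8)
})

test_that("outcome models include/exclude the det-limit and interaction terms", {
  set.seed(105)
  cfg <- sim_config(seed = 105, n_soil = 150)
  st <- simulate_study(cfg)
  sdat <- data.frame(x = st$soil$x, y = st$soil$y, z = log10(st$soil$hg_mgkg))
  fit <- edkrige(sdat, st$canal, n_starts = 1)
  fits <- run_outcome_models(st$participants, soil = st$soil, model = fit,
                             which = c("urine_measured", "urine_predicted"),
                             ci_variances = FALSE)
  tm <- fits$urine_measured$beta$term
  tp <- fits$urine_predicted$beta$term
  expect_true("below_det_limit" %in% tm)
  expect_true("age:mother" %in% tm)
  expect_false("below_det_limit" %in% tp)
  expect_false("age:mother" %in% tp)
  rep_m <- attr(fits, "reports")$urine_measured
  expect_true(all(c("sigma2_family", "sigma2_resid") %in% rep_m$variable))
})

test_that("identical exposure columns give identical fits regardless of label", {
  rec <- sim_records(20, 3, seed = 106)
  rec$exposure <- runif(nrow(rec))
  r1 <- rec; attr(r1, "exposure_kind") <- "measured"
  r2 <- rec; attr(r2, "exposure_kind") <- "predicted"
  f1 <- hbm_lmm(r1, ci_variances = FALSE)
  f2 <- hbm_lmm(r2, ci_variances = FALSE)
  expect_equal(f1$beta$estimate, f2$beta$estimate, tolerance = 1e-10)
})
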