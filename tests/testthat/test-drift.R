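test_that("drift designs match their definitions", {
  expect_equal(unname(build_drift_design(2, drift_spec("quadratic"))[1, ]),
               c(1, 2, 4))
  bs <- drift_spec("broken_stick", breakpoint = 2)
  expect_equal(unname(build_drift_design(c(1.5, 3), bs)[, 3]), c(0, 1))
  expect_equal(unname(build_drift_design(1, drift_spec("inverse"))[1, 3]), 0.5)
  expect_equal(ncol(build_drift_design(1:3, drift_spec("linear"))), 2)
  expect_error(build_drift_design(-1, drift_spec("inverse")), "undefined")
})

test_that("OLS drift fit recovers exact linear data and the closed-form AIC", {
  d <- seq(0, 3, length.out = 20)
  y <- 1.5 - 0.8 * d
  f <- suppressWarnings(fit_drift_ols(y, d, drift_spec("linear")))
  expect_equal(unname(coef(f)), c(1.5, -0.8), tolerance = 1e-10)
  expect_lt(f$sigma2, 1e-20)

  # toy n=10: AIC = 2k - 2 logL with the closed-form Gaussian logL at the
  # MLE variance, k = coefficients + 1 for the variance
  set.seed(5)
  d <- runif(10, 0, 3)
  y <- 2 - d + rnorm(10, sd = 0.3)
  f <- fit_drift_ols(y, d, drift_spec("quadratic"))
  X <- cbind(1, d, d^2)
  b <- solve(crossprod(X), crossprod(X, y))
  s2 <- mean((y - X %*% b)^2)
  logL <- sum(dnorm(y, X %*% b, sqrt(s2), log = TRUE))
  k <- 4
  expect_equal(f$aic, 2 * k - 2 * logL, tolerance = 1e-10)
  expect_equal(f$bic, k * log(10) - 2 * logL, tolerance = 1e-10)
})

test_that("adding a drift column never increases the residual sum of squares", {
  set.seed(8)
  d <- runif(60, 0, 3)
  y <- 2 - 1.5 * d + 0.2 * d^2 + rnorm(60, sd = 0.4)
  rss <- function(spec) {
    f <- fit_drift_ols(y, d, spec)
    sum(residuals(f$lm)^2)
  }
  expect_lte(rss(drift_spec("quadratic")), rss(drift_spec("linear")) + 1e-12)
  expect_lte(rss(drift_spec("broken_stick")), rss(drift_spec("linear")) + 1e-12)
  expect_lte(rss(drift_spec("inverse")), rss(drift_spec("linear")) + 1e-12)
})

test_that("linear fit equals quadratic fit with zero quadratic coefficient", {
  set.seed(9)
  d <- runif(40, 0, 3)
  y <- 1 - 0.5 * d + rnorm(40, sd = 0.2)
  lin <- fit_drift_ols(y, d, drift_spec("linear"))
  # constrained 'quadratic': same data, quadratic column zeroed -> identical
  # likelihood once k is adjusted down by one
  X <- cbind(1, d)
  b <- solve(crossprod(X), crossprod(X, y))
  s2 <- mean((y - X %*% b)^2)
  logL <- sum(dnorm(y, X %*% b, sqrt(s2), log = TRUE))
  expect_equal(lin$aic, 2 * 3 - 2 * logL, tolerance = 1e-10)
})

test_that("AIC selection prefers the generating quadratic and applies tie rules", {
  # published AIC ordering: quadratic wins
  mk <- function(kind, aic, p) {
    structure(list(spec = drift_spec(kind), aic = aic,
                   coefficients = data.frame(term = seq_len(p))),
              class = "drift_fit")
  }
  fits <- list(mk("linear", 3435, 2), mk("quadratic", 3393, 3),
               mk("broken_stick", 3423, 3), mk("inverse", 3399, 3))
  expect_equal(select_drift(fits)$kind, "quadratic")
  # equal AIC: fewer parameters wins
  expect_equal(select_drift(list(mk("quadratic", 100, 3),
                                 mk("linear", 100, 2)))$kind, "linear")
  # single fit: returned as-is
  expect_equal(select_drift(list(mk("inverse", 5, 3)))$kind, "inverse")
  expect_error(select_drift(list()), "no drift fits")
})

test_that("drift_table fits all four candidates on simulated quadratic data", {
  set.seed(21)
  d <- runif(400, 0, 3)
  y <- 2.34 - 2.23 * d + 0.38 * d^2 + rnorm(400, sd = 0.5)
  dt <- drift_table(y, d)
  expect_setequal(dt$comparison$model,
                  c("linear", "quadratic", "broken_stick", "inverse"))
  expect_equal(select_drift(dt)$kind, "quadratic")
})
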