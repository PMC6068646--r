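canal <- toy_canal()

test_that("with both variances fixed at zero the fit reduces to OLS", {
  set.seed(31)
  dat <- toy_field(80, variogram_params(0.2, 0.01, 40), seed = 31)
  vp0 <- structure(list(sigma2 = 0, tau2 = 0, alpha = 50, gamma = 0.5),
                   class = "variogram_params")
  fit <- edkrige(dat, canal, vp = vp0)
  ld <- log_distance(distance_to_polyline(dat$x, dat$y, canal))
  ols <- fit_drift_ols(dat$z, ld, drift_spec("quadratic"))
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 1e-8)
})

test_that("with zero nugget, prediction at sampled sites interpolates exactly", {
  set.seed(32)
  dat <- toy_field(40, variogram_params(0.3, 0, 60), seed = 32)
  fit <- edkrige(dat, canal, vp = variogram_params(0.3, 0, 60, 0.5))
  pr <- predict(fit, dat[, c("x", "y")])
  expect_equal(pr$mean, dat$z, tolerance = 1e-6)
  expect_true(all(pr$se < 1e-4))
})

test_that("with zero sill, prediction is the drift regression with its SE", {
  set.seed(33)
  dat <- toy_field(60, variogram_params(0.2, 0.05, 40), seed = 33)
  tau2 <- 0.04
  fit <- edkrige(dat, canal, vp = variogram_params(0, tau2, 50, 0.5))
  targets <- data.frame(x = c(100, 700), y = c(50, 300))
  pr <- predict(fit, targets)
  ld <- log_distance(distance_to_polyline(dat$x, dat$y, canal))
  X <- build_drift_design(ld, drift_spec("quadratic"))
  ld0 <- log_distance(distance_to_polyline(targets$x, targets$y, canal))
  X0 <- build_drift_design(ld0, drift_spec("quadratic"))
  b <- solve(crossprod(X), crossprod(X, dat$z))
  expect_equal(pr$mean, drop(X0 %*% b), tolerance = 1e-8)
  se_reg <- sqrt(tau2 * diag(X0 %*% solve(crossprod(X)) %*% t(X0)))
  expect_equal(pr$se, se_reg, tolerance = 1e-8)
})

test_that("kriging matches the dense-matrix BLUP oracle on small instances", {
  set.seed(34)
  vp <- variogram_params(0.32, 0.003, 46.67, 0.5)
  dat <- toy_field(15, vp, seed = 34)
  fit <- edkrige(dat, canal, vp = vp)
  ld <- log_distance(distance_to_polyline(dat$x, dat$y, canal))
  X <- build_drift_design(ld, drift_spec("quadratic"))
  for (i in 1:5) {
    xy0 <- c(runif(1, 0, 1000), runif(1, 0, 400))
    ld0 <- log_distance(distance_to_polyline(xy0[1], xy0[2], canal))
    x0 <- drop(build_drift_design(ld0, drift_spec("quadratic")))
    want <- oracle_ukrige(cbind(dat$x, dat$y), dat$z, X, x0, xy0, vp)
    got <- predict(fit, data.frame(x = xy0[1], y = xy0[2]))
    expect_equal(got$mean, want$mean, tolerance = 1e-8)
    expect_equal(got$se^2, want$var, tolerance = 1e-8)
  }
})

test_that("exact drift data with vanishing variances reproduces the drift", {
  set.seed(35)
  xy <- cbind(runif(30, 0, 1000), runif(30, 0, 400))
  ld <- log_distance(distance_to_polyline(xy[, 1], xy[, 2], canal))
  beta <- c(2.34, -2.23, 0.38)
  z <- drop(build_drift_design(ld, drift_spec("quadratic")) %*% beta)
  fit <- edkrige(data.frame(x = xy[, 1], y = xy[, 2], z = z), canal,
                 vp = variogram_params(1e-10, 1e-12, 50, 0.5))
  tg <- data.frame(x = c(5, 333, 900), y = c(5, 200, 390))
  ld0 <- log_distance(distance_to_polyline(tg$x, tg$y, canal))
  want <- drop(build_drift_design(ld0, drift_spec("quadratic")) %*% beta)
  expect_equal(predict(fit, tg)$mean, want, tolerance = 1e-4)
})

test_that("the REML optimum beats random variance-parameter points", {
  set.seed(36)
  vp <- variogram_params(0.32, 0.003, 46.67, 0.5)
  dat <- toy_field(100, vp, seed = 36)
  fit <- edkrige(dat, canal)
  at_fit <- reml_neg2loglik(dat, canal, fit$vp$sigma2, fit$vp$tau2,
                            fit$vp$alpha)
  for (i in 1:20) {
    cand <- reml_neg2loglik(dat, canal,
                            sigma2 = runif(1, 0.01, 1),
                            tau2 = runif(1, 0, 0.3),
                            alpha = runif(1, 5, 400))
    expect_gte(cand, at_fit - 1e-6)
  }
})

test_that("prediction variance is nonnegative and shrinks with new data at the target", {
  set.seed(37)
  vp <- variogram_params(0.3, 0.02, 50, 0.5)
  dat <- toy_field(50, vp, seed = 37)
  fit <- edkrige(dat, canal, vp = vp)
  tg <- data.frame(x = 450, y = 120)
  pr1 <- predict(fit, tg)
  expect_gte(pr1$se, 0)
  dat2 <- rbind(dat, data.frame(x = 450, y = 120, z = pr1$mean))
  fit2 <- edkrige(dat2, canal, vp = vp)
  pr2 <- predict(fit2, tg)
  expect_lte(pr2$se, pr1$se + 1e-10)
})

test_that("duplicated locations are jittered with a warning", {
  set.seed(38)
  dat <- toy_field(30, variogram_params(0.3, 0.01, 50), seed = 38)
  dat2 <- rbind(dat, dat[1:3, ])
  expect_warning(fit <- edkrige(dat2, canal, vp = variogram_params(0.3, 0.01, 50, 0.5)),
                 "jittered")
  expect_s3_class(fit, "edk")
})

test_that("whitened residuals are near standard normal on simulated data", {
  vp <- variogram_params(0.32, 0.02, 46.67, 0.5)
  dat <- toy_field(500, vp, seed = 39, box = c(0, 2000, 0, 800))
  fit <- edkrige(dat, canal)
  w <- residuals(fit, "whitened")
  expect_length(w, 500)
  expect_lt(abs(var(w) - 1), 0.2)
  qq <- qq_residuals(fit)
  sl <- coef(lm(qq$observed ~ qq$theoretical))[2]
  expect_lt(abs(sl - 1), 0.1)
  # monotone in both coordinates by construction
  expect_true(all(diff(qq$theoretical) >= 0))
  expect_true(all(diff(qq$observed) >= 0))
})

test_that("grid prediction matches pointwise prediction and flags sparse areas", {
  set.seed(40)
  vp <- variogram_params(0.3, 0.01, 50, 0.5)
  # cluster all samples on the left half
  xy <- cbind(runif(80, 0, 400), runif(80, 0, 400))
  d <- distance_to_polyline(xy[, 1], xy[, 2], canal)
  ld <- log10(pmax(d, 1))
  z <- 2 - ld + rnorm(80, sd = 0.3)
  dat <- data.frame(x = xy[, 1], y = xy[, 2], z = z)
  fit <- edkrige(dat, canal, vp = vp)
  # one-cell grid equals point prediction at the center
  g1 <- predict_grid(fit, c(0, 100, 0, 100), 100)
  p1 <- predict(fit, data.frame(x = 50, y = 50))
  expect_equal(g1$mean, p1$mean)
  expect_equal(g1$se, p1$se)
  # SE higher far from the data than on top of it
  g <- predict_grid(fit, c(0, 1000, 0, 400), 50)
  dmin <- apply(cbind(g$x, g$y), 1, function(p)
    min(sqrt((dat$x - p[1])^2 + (dat$y - p[2])^2)))
  expect_gt(mean(g$se[dmin >= 100]), mean(g$se[dmin <= 20]))
  # cell-count cap
  expect_error(predict_grid(fit, c(0, 1000, 0, 400), 1, max_cells = 1000),
               "cap")
})

test_that("grid means are constant when the drift is flat and data constant-mean", {
  # flat field (intercept-only variability), tau2 = 0: means stay near the
  # field surface; with a constant response the interpolator returns it
  set.seed(41)
  xy <- cbind(runif(25, 0, 500), runif(25, 0, 300))
  dat <- data.frame(x = xy[, 1], y = xy[, 2], z = rep(1.7, 25))
  fit <- edkrige(dat, canal, vp = variogram_params(0.3, 0, 50, 0.5))
  g <- predict_grid(fit, c(0, 500, 0, 300), 100)
  expect_equal(g$mean, rep(1.7, nrow(g)), tolerance = 1e-6)
})
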