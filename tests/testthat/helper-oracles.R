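# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive implementations (dense sampling, double loops,
# textbook matrix formulas) kept separate from the package's code paths.

# minimum distance to a polyline by dense sampling of its vertices
oracle_polyline_distance <- function(px, py, vxy, n_dense = 1e5) {
  seg_len <- sqrt(diff(vxy[, 1])^2 + diff(vxy[, 2])^2)
  cum <- c(0, cumsum(seg_len))
  t <- seq(0, sum(seg_len), length.out = n_dense)
  seg <- pmin(findInterval(t, cum, rightmost.closed = TRUE), length(seg_len))
  frac <- (t - cum[seg]) / seg_len[seg]
  qx <- vxy[seg, 1] + frac * (vxy[seg + 1, 1] - vxy[seg, 1])
  qy <- vxy[seg, 2] + frac * (vxy[seg + 1, 2] - vxy[seg, 2])
  min(sqrt((qx - px)^2 + (qy - py)^2))
}

# all-pairs double-loop Matheron estimator
oracle_matheron <- function(x, y, z, edges) {
  n <- length(x)
  nb <- length(edges) - 1
  ssq <- numeric(nb); cnt <- integer(nb)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      h <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      b <- NA
      for (k in seq_len(nb)) if (h > edges[k] && h <= edges[k + 1]) b <- k
      if (!is.na(b)) {
        ssq[b] <- ssq[b] + (z[i] - z[j])^2
        cnt[b] <- cnt[b] + 1L
      }
    }
  }
  list(gamma = ifelse(cnt > 0, ssq / (2 * cnt), NA), n_pairs = cnt)
}

# universal kriging mean/variance from the textbook augmented system:
#   [ Sigma  X ] [lambda]   [c0]
#   [ X'     0 ] [  mu  ] = [x0]
# predictor lambda' y, variance sigma2 - lambda' c0 - mu' x0
oracle_ukrige <- function(xy, y, X, x0, xy0, vp, gamma = 0.5) {
  n <- nrow(xy)
  D <- as.matrix(dist(xy))
  Sigma <- vp$sigma2 * exp(-(D / vp$alpha)^gamma) + vp$tau2 * diag(n)
  d0 <- sqrt((xy[, 1] - xy0[1])^2 + (xy[, 2] - xy0[2])^2)
  c0 <- vp$sigma2 * exp(-(d0 / vp$alpha)^gamma)
  p <- ncol(X)
  A <- rbind(cbind(Sigma, X), cbind(t(X), matrix(0, p, p)))
  sol <- solve(A, c(c0, x0))
  lambda <- sol[1:n]; mu <- sol[n + 1:p]
  list(mean = sum(lambda * y),
       var = vp$sigma2 - sum(lambda * c0) - sum(mu * x0))
}

# closed-form ANOVA estimator of the balanced one-way random-effects model
# (a groups, m observations each): sigma2_e = MSW, sigma2_b = (MSB - MSW)/m
oracle_anova_varcomp <- function(y, group) {
  m <- table(group)
  stopifnot(length(unique(m)) == 1)
  m <- unname(m[1])
  a <- length(unique(group))
  gm <- mean(y)
  grp_means <- tapply(y, group, mean)
  msb <- m * sum((grp_means - gm)^2) / (a - 1)
  msw <- sum((y - grp_means[as.character(group)])^2) / (a * (m - 1))
  list(mean = gm, sigma2_b = (msb - msw) / m, sigma2_e = msw)
}

# small helpers -------------------------------------------------------------

toy_canal <- function() polyline(c(0, 1000), c(0, 0))

# small Gaussian field with quadratic drift around a straight canal,
# simulated directly (independent of the package generator)
toy_field <- function(n, vp, beta = c(2.34, -2.23, 0.38), seed = NULL,
                      box = c(0, 1000, 0, 400), canal = toy_canal()) {
  if (!is.null(seed)) set.seed(seed)
  xy <- cbind(runif(n, box[1], box[2]), runif(n, box[3], box[4]))
  d <- distance_to_polyline(xy[, 1], xy[, 2], canal)
  ld <- log10(pmax(d, 1))
  X <- cbind(1, ld, ld^2)
  D <- as.matrix(dist(xy))
  C <- vp$sigma2 * exp(-(D / vp$alpha)^vp$gamma)
  L <- chol(C + diag(1e-10, n))
  z <- drop(X %*% beta) + drop(t(L) %*% rnorm(n)) + rnorm(n, sd = sqrt(vp$tau2))
  data.frame(x = xy[, 1], y = xy[, 2], z = z)
}
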