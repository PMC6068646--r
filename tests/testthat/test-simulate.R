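test_that("soil simulation is deterministic in the seed", {
  cfg <- sim_config(seed = 201, n_soil = 80)
  s1 <- simulate_soil(cfg)
  s2 <- simulate_soil(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_soil(sim_config(seed = 202, n_soil = 80))
  expect_false(identical(s1$hg_mgkg, s3$hg_mgkg))
})

test_that("with zero variances the field is a deterministic drift function", {
  cfg <- sim_config(seed = 203, n_soil = 60,
                    vp = variogram_params(0, 0, 46.67, 0.5))
  s <- simulate_soil(cfg)
  canal <- sim_canal(cfg)
  ld <- log_distance(distance_to_polyline(s$x, s$y, canal))
  mu <- drop(build_drift_design(ld, drift_spec("quadratic")) %*% cfg$drift_beta)
  expect_equal(attr(s, "true_z"), mu, tolerance = 1e-12)
})

test_that("soil values are positive with LOD applied consistently", {
  cfg <- sim_config(seed = 204, n_soil = 150)
  s <- simulate_soil(cfg)
  expect_true(all(s$hg_mgkg > 0))
  redo <- substitute_lod(10^attr(s, "true_z"), cfg$lod)
  expect_equal(s$hg_mgkg, as.numeric(redo))
  expect_equal(s$below_lod, unname(attr(redo, "below_lod")))
})

test_that("sampling is denser near the canal", {
  cfg <- sim_config(seed = 205, n_soil = 600)
  s <- simulate_soil(cfg)
  d <- distance_to_polyline(s$x, s$y, sim_canal(cfg))
  # 60% targeted near the canal plus uniform spillover
  expect_gt(mean(d <= cfg$near_dist), 0.55)
})

test_that("cohort structure: 64 families, 107 children, within-family correlation", {
  cfg <- sim_config(seed = 206, n_soil = 60)
  st <- simulate_study(cfg)
  p <- st$participants
  expect_equal(length(unique(p$family_id)), 64)
  expect_equal(sum(p$mother == 1), 64)
  expect_equal(sum(p$mother == 0), 107)
  expect_true(all(p$age[p$mother == 1] >= 25 & p$age[p$mother == 1] <= 45))
  expect_true(all(p$age[p$mother == 0] >= 2 & p$age[p$mother == 0] <= 11))
  # shared family intercept induces within-family covariance in outcomes
  truth <- attr(p, "truth")
  fam_means <- tapply(truth$log_urine, p$family_id, mean)
  expect_gt(var(fam_means), 0)
  # residences shared within family
  expect_equal(length(unique(paste(p$x, p$y))), 64)
})

test_that("within-family outcome covariance exceeds between-family covariance", {
  cfg <- sim_config(seed = 207, n_soil = 60, urine_family_sd = 0.4,
                    urine_resid_sd = 0.2)
  st <- simulate_study(cfg)
  p <- st$participants
  y <- log10(p$urine_hg / p$creatinine)
  resid <- y - mean(y)
  fams <- split(resid, p$family_id)
  within <- unlist(lapply(fams, function(v) {
    if (length(v) < 2) return(NULL)
    pr <- combn(length(v), 2)
    v[pr[1, ]] * v[pr[2, ]]
  }))
  # raw product moments confound the drift; just require clearly positive
  expect_gt(mean(within), 0)
})

test_that("fixture suite writes consistent files and a complete manifest", {
  out <- tempfile("fix")
  files <- suppressMessages(make_fixture_suite(out, scales = "small"))
  expect_true(all(file.exists(files$small)))
  man <- yaml::read_yaml(files$manifest)
  expect_equal(man$small$seed, 101)
  expect_equal(man$small$variogram$sill, 0.32)
  soil <- read_soil_csv(files$small[["soil"]])
  expect_true(any(soil$depth_layer != "0-20 cm"))  # exercises the filter
  parts <- read_participants_csv(files$small[["participants"]])
  expect_equal(length(unique(parts$family_id)), 20)
  canal <- read_canal(files$small[["canal"]])
  expect_s3_class(canal, "polyline")
  # regeneration is byte-identical
  out2 <- tempfile("fix2")
  files2 <- suppressMessages(make_fixture_suite(out2, scales = "small"))
  expect_identical(readLines(files$small[["soil"]]),
                   readLines(files2$small[["soil"]]))
})

test_that("the generator's field is recoverable by the REML fit", {
  cfg <- sim_config(seed = 208, n_soil = 400)
  s <- simulate_soil(cfg)
  sdat <- data.frame(x = s$x, y = s$y, z = log10(s$hg_mgkg))
  fit <- edkrige(sdat, sim_canal(cfg), n_starts = 2)
  expect_lt(abs(fit$beta[["(Intercept)"]] - 2.34) / 2.34, 0.3)
  expect_lt(abs(fit$vp$sigma2 - 0.32) / 0.32, 0.6)
  expect_lt(abs(fit$vp$alpha - 46.67) / 46.67, 0.8)
})
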