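#' Simulation configuration for the synthetic study
#'
#' Bundles every parameter of the synthetic soil field and cohort. The
#' defaults reproduce the statistical structure of the study the package
#' is designed for: ~3000 topsoil samples whose log10 mercury follows a
#' quadratic drift in log10 distance to a canal
#' (`beta = (2.34, -2.23, 0.38)`) plus a stationary Gaussian field with
#' stable exponential covariance (sill 0.32, nugget 0.003, range 46.67 m,
#' shape 0.5), and a cohort of 64 families (64 mothers, 107 children)
#' whose log10 urine and hair outcomes follow the family random-intercept
#' regressions with the published coefficient values.
#'
#' @param seed Integer seed recorded with the configuration.
#' @param n_soil Number of topsoil samples.
#' @param bbox Study region `c(xmin, xmax, ymin, ymax)` in meters.
#' @param canal_xy Two-column matrix of canal vertices; default a
#'   5-vertex polyline running lengthwise through the region.
#' @param frac_near,near_dist Sampling-intensity mixture: fraction of
#'   samples placed within `near_dist` meters of the canal (the canal
#'   neighborhood was sampled more densely), remainder uniform.
#' @param drift_beta Quadratic drift coefficients (intercept, logdist,
#'   logdist^2) on the log10 mg/kg scale.
#' @param vp True [variogram_params()] of the field.
#' @param lod Limit of determination, mg/kg.
#' @param dist_floor Clamp for [log_distance()].
#' @param parcel_size Edge (m) of the square parcels used as parcel IDs.
#' @param extra_deep_frac Fraction of additional non-topsoil samples
#'   emitted (default 0; used by fixtures to exercise the depth filter).
#' @param n_families,n_children Cohort sizes; children are allocated at
#'   least one per family and counts are conditioned to sum to
#'   `n_children`.
#' @param urine_coef,hair_coef Named outcome-model coefficients (see
#'   defaults in the source; names match the encoded covariates, plus
#'   `intercept`, `exposure`, `below_det_limit`, `age_mother`).
#' @param urine_family_sd,urine_resid_sd,hair_family_sd,hair_resid_sd
#'   Random-intercept and residual SDs on the log10 scale.
#' @param creatinine_frac_out Fraction of participants whose creatinine is
#'   drawn outside the validity range (exercises the exclusion rule).
#' @return Object of class `"sim_config"` (a list).
#' @export
sim_config <- function(seed = 1, n_soil = 3000,
                       bbox = c(0, 4000, 0, 1200),
                       canal_xy = cbind(c(0, 900, 2100, 3100, 4000),
                                        c(620, 560, 640, 580, 610)),
                       frac_near = 0.6, near_dist = 200,
                       drift_beta = c(2.34, -2.23, 0.38),
                       vp = variogram_params(0.32, 0.003, 46.67, 0.5),
                       lod = 0.1, dist_floor = 1, parcel_size = 200,
                       extra_deep_frac = 0,
                       n_families = 64, n_children = 107,
                       urine_coef = c(intercept = -0.4, exposure = 0.02,
                                      age = -0.04, mother = -0.97,
                                      amalgam_sqrt = 0.33, seafish_sqrt = 0.08,
                                      seafish_last3d = 0.32, smoking = 0.30,
                                      near_sea = -0.01, vegetables = 0.07,
                                      below_det_limit = -0.08,
                                      age_mother = 0.05),
                       hair_coef = c(intercept = -0.8, exposure = 0.05,
                                     age = 0.01, mother = -0.67,
                                     amalgam_sqrt = 0.04, seafish_sqrt = 0.17,
                                     smoking = 0.12, near_sea = 0.19,
                                     vegetables = 0.06, hair_dyeing = -0.19,
                                     below_det_limit = -0.02,
                                     age_mother = 0.01),
                       urine_family_sd = sqrt(0.03),
                       urine_resid_sd = sqrt(0.06),
                       hair_family_sd = sqrt(0.01),
                       hair_resid_sd = sqrt(0.11),
                       creatinine_frac_out = 0.03) {
  stopifnot(n_soil >= 10, frac_near >= 0, frac_near <= 1,
            vp$sigma2 >= 0, vp$tau2 >= 0,
            urine_family_sd >= 0, urine_resid_sd >= 0,
            hair_family_sd >= 0, hair_resid_sd >= 0)
  cfg <- list(seed = seed, n_soil = n_soil, bbox = bbox, canal_xy = canal_xy,
              frac_near = frac_near, near_dist = near_dist,
              drift_beta = drift_beta, vp = vp, lod = lod,
              dist_floor = dist_floor, parcel_size = parcel_size,
              extra_deep_frac = extra_deep_frac,
              n_families = n_families, n_children = n_children,
              urine_coef = urine_coef, hair_coef = hair_coef,
              urine_family_sd = urine_family_sd, urine_resid_sd = urine_resid_sd,
              hair_family_sd = hair_family_sd, hair_resid_sd = hair_resid_sd,
              creatinine_frac_out = creatinine_frac_out)
  class(cfg) <- "sim_config"
  cfg
}

#' Canal polyline of a simulation configuration
#' @param cfg A [sim_config()].
#' @return A [polyline()].
#' @export
sim_canal <- function(cfg) polyline(cfg$canal_xy)

parcel_label <- function(x, y, size) {
  sprintf("P%04d_%04d", floor(x / size), floor(y / size))
}

# random point on the canal plus a perpendicular offset
sample_near_canal <- function(n, canal, max_offset, bbox) {
  v <- canal$vertices
  seg_len <- sqrt(diff(v[, 1])^2 + diff(v[, 2])^2)
  seg <- sample.int(length(seg_len), n, replace = TRUE, prob = seg_len)
  t <- stats::runif(n)
  px <- v[seg, 1] + t * (v[seg + 1, 1] - v[seg, 1])
  py <- v[seg, 2] + t * (v[seg + 1, 2] - v[seg, 2])
  nx <- -(v[seg + 1, 2] - v[seg, 2]) / seg_len[seg]
  ny <- (v[seg + 1, 1] - v[seg, 1]) / seg_len[seg]
  off <- stats::runif(n, -max_offset, max_offset)
  cbind(pmin(pmax(px + off * nx, bbox[1]), bbox[2]),
        pmin(pmax(py + off * ny, bbox[3]), bbox[4]))
}

# exact Gaussian-field draw (Cholesky) at the given locations
draw_field <- function(xy, vp) {
  n <- nrow(xy)
  if (vp$sigma2 == 0) return(numeric(n))
  C <- stable_exponential_cov(as.matrix(stats::dist(xy)), vp)
  L <- tryCatch(chol(C), error = function(e) {
    tryCatch(chol(C + diag(1e-10 * vp$sigma2, n)),
             error = function(e2) stop("Cholesky factorization failed"))
  })
  drop(t(L) %*% stats::rnorm(n))
}

#' Simulate the synthetic soil-mercury field
#'
#' Draws sample locations (densely near the canal per the sampling
#' mixture), evaluates the quadratic drift in log10 distance, adds an
#' exact Cholesky draw of the Gaussian random field and iid nugget noise,
#' back-transforms to mg/kg and applies the limit-of-determination rule.
#'
#' @param cfg A [sim_config()]. The RNG is seeded from `cfg$seed`.
#' @param extra_xy Optional matrix of additional locations (e.g.
#'   residences); the field is simulated jointly there and the true log10
#'   values are returned in the `extra_z` attribute.
#' @param reseed Seed the RNG from `cfg$seed` (default); [simulate_study()]
#'   disables this to keep one coherent stream.
#' @return Data frame `x`, `y`, `hg_mgkg`, `depth_layer`, `parcel_id`,
#'   `below_lod`, with attributes `true_z` (log10 values before LOD
#'   substitution), `extra_z`, and `cfg`.
#' @export
simulate_soil <- function(cfg, extra_xy = NULL, reseed = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  if (reseed) set.seed(cfg$seed)
  canal <- sim_canal(cfg)
  n <- cfg$n_soil
  n_near <- round(cfg$frac_near * n)
  xy_near <- sample_near_canal(n_near, canal, cfg$near_dist, cfg$bbox)
  xy_far <- cbind(stats::runif(n - n_near, cfg$bbox[1], cfg$bbox[2]),
                  stats::runif(n - n_near, cfg$bbox[3], cfg$bbox[4]))
  xy <- rbind(xy_near, xy_far)
  m <- if (is.null(extra_xy)) 0L else nrow(extra_xy)
  all_xy <- rbind(xy, extra_xy)

  ld <- log_distance(distance_to_polyline(all_xy[, 1], all_xy[, 2], canal),
                     cfg$dist_floor)
  mu <- drop(build_drift_design(ld, drift_spec("quadratic")) %*% cfg$drift_beta)
  field <- draw_field(all_xy, cfg$vp)
  noise <- stats::rnorm(n + m, sd = sqrt(cfg$vp$tau2))
  z <- mu + field + noise
  z_soil <- z[seq_len(n)]

  hg <- substitute_lod(10^z_soil, cfg$lod)
  soil <- data.frame(x = xy[, 1], y = xy[, 2], hg_mgkg = as.numeric(hg),
                     depth_layer = "0-20 cm",
                     parcel_id = parcel_label(xy[, 1], xy[, 2], cfg$parcel_size),
                     below_lod = attr(hg, "below_lod"))
  if (cfg$extra_deep_frac > 0) {
    nd <- ceiling(cfg$extra_deep_frac * n)
    idx <- sample.int(n, nd)
    deep_z <- z_soil[idx] - 0.3 + stats::rnorm(nd, sd = 0.2)
    dhg <- substitute_lod(10^deep_z, cfg$lod)
    deep <- data.frame(x = xy[idx, 1], y = xy[idx, 2],
                       hg_mgkg = as.numeric(dhg),
                       depth_layer = sample(c("20-40 cm", "deeper"), nd, TRUE),
                       parcel_id = parcel_label(xy[idx, 1], xy[idx, 2],
                                                cfg$parcel_size),
                       below_lod = attr(dhg, "below_lod"))
    soil <- rbind(soil, deep)
  }
  attr(soil, "true_z") <- z_soil
  attr(soil, "extra_z") <- if (m) z[n + seq_len(m)] else NULL
  attr(soil, "cfg") <- cfg
  soil
}

# children-per-family counts, conditioned to sum to the target
children_counts <- function(n_families, n_children) {
  k <- 1 + stats::rpois(n_families, max(n_children / n_families - 1, 0.01))
  while (sum(k) != n_children) {
    j <- sample.int(n_families, 1)
    if (sum(k) > n_children && k[j] > 1) k[j] <- k[j] - 1
    if (sum(k) < n_children) k[j] <- k[j] + 1
  }
  k
}

#' Simulate the participant cohort
#'
#' Families are placed at random residences in the study region; each has
#' one mother (age 25-45) and one or more children (ages 2-11). Encoded
#' questionnaire covariates are drawn from documented distributions
#' (amalgam fillings: Poisson, mean 2 for mothers / 0.2 for children;
#' sea-fish portions: Poisson mean 3; recent sea fish: Bernoulli 0.3;
#' smoking: mothers only, Bernoulli 0.25; birth country near the sea and
#' regional vegetables: family-level Bernoulli 0.2 / 0.4; hair dyeing:
#' Bernoulli 0.3 mothers / 0.02 children). Log10 urine and hair outcomes
#' follow the configured linear mixed models with a shared family
#' intercept; urinary concentrations are back-multiplied by a creatinine
#' draw so the creatinine-adjustment rule is exercised end to end.
#'
#' @param cfg A [sim_config()].
#' @param residence_xy `n_families x 2` matrix of residences.
#' @param exposure_z True log10 soil value at each residence (one per
#'   family), e.g. from the `extra_z` attribute of [simulate_soil()].
#' @return Participant data frame (one row each for mothers and children)
#'   with a `truth` attribute carrying the generating values.
#' @export
simulate_participants <- function(cfg, residence_xy, exposure_z) {
  stopifnot(inherits(cfg, "sim_config"),
            nrow(residence_xy) == cfg$n_families,
            length(exposure_z) == cfg$n_families)
  nf <- cfg$n_families
  kids <- children_counts(nf, cfg$n_children)
  fam <- c(seq_len(nf), rep(seq_len(nf), kids))
  mother <- c(rep(1, nf), rep(0, sum(kids)))
  np <- length(fam)
  age <- ifelse(mother == 1, stats::runif(np, 25, 45), stats::runif(np, 2, 11))

  amalgam <- stats::rpois(np, ifelse(mother == 1, 2, 0.2))
  seafish <- stats::rpois(np, 3)
  last3d <- stats::rbinom(np, 1, 0.3)
  smoking <- ifelse(mother == 1, stats::rbinom(np, 1, 0.25), 0)
  near_sea_f <- stats::rbinom(nf, 1, 0.2)
  veg_f <- stats::rbinom(nf, 1, 0.4)
  hair_dye <- stats::rbinom(np, 1, ifelse(mother == 1, 0.3, 0.02))

  expo <- exposure_z[fam]
  below <- as.numeric(expo < log10(cfg$lod))

  covs <- function(coef) {
    coef[["intercept"]] +
      coef[["exposure"]] * expo +
      coef[["age"]] * age +
      coef[["mother"]] * mother +
      coef[["amalgam_sqrt"]] * sqrt(amalgam) +
      coef[["seafish_sqrt"]] * sqrt(seafish) +
      (if (!is.na(coef["seafish_last3d"])) coef[["seafish_last3d"]] * last3d else 0) +
      coef[["smoking"]] * smoking +
      coef[["near_sea"]] * near_sea_f[fam] +
      coef[["vegetables"]] * veg_f[fam] +
      (if (!is.na(coef["hair_dyeing"])) coef[["hair_dyeing"]] * hair_dye else 0) +
      coef[["below_det_limit"]] * below +
      coef[["age_mother"]] * age * mother
  }
  b_urine <- stats::rnorm(nf, sd = cfg$urine_family_sd)
  b_hair <- stats::rnorm(nf, sd = cfg$hair_family_sd)
  log_urine <- covs(cfg$urine_coef) + b_urine[fam] +
    stats::rnorm(np, sd = cfg$urine_resid_sd)
  log_hair <- covs(cfg$hair_coef) + b_hair[fam] +
    stats::rnorm(np, sd = cfg$hair_resid_sd)

  # creatinine: mostly in-range lognormal, a configured fraction outside
  creat <- exp(stats::rnorm(np, 0, 0.3))
  creat <- pmin(pmax(creat, 0.35), 2.9)
  out_idx <- which(stats::runif(np) < cfg$creatinine_frac_out)
  creat[out_idx] <- sample(c(0.1, 4), length(out_idx), replace = TRUE)

  p <- data.frame(
    id = sprintf("ID%03d", seq_len(np)),
    family_id = sprintf("F%03d", fam),
    mother = mother, age = age,
    x = residence_xy[fam, 1], y = residence_xy[fam, 2],
    parcel_id = parcel_label(residence_xy[fam, 1], residence_xy[fam, 2],
                             cfg$parcel_size),
    urine_hg = 10^log_urine * creat,
    creatinine = creat,
    hair_hg = 10^log_hair,
    amalgam_count = amalgam,
    seafish_portions_30d = seafish,
    seafish_last3d = last3d,
    smoking = smoking,
    birth_country_near_sea = near_sea_f[fam],
    eats_vegetables_region = veg_f[fam],
    hair_dyeing_6m = hair_dye)
  attr(p, "truth") <- list(exposure_z = expo, log_urine = log_urine,
                           log_hair = log_hair, b_urine = b_urine,
                           b_hair = b_hair, kids = kids)
  p
}

#' Simulate a complete synthetic study
#'
#' Joint simulation of the soil field and the cohort: the Gaussian field
#' is drawn once, jointly, at all sample locations and residences, so the
#' exposures driving the outcomes are the field's true values at the
#' homes.
#'
#' @param cfg A [sim_config()].
#' @return List: `soil` (data frame), `participants` (data frame),
#'   `canal` ([polyline()]), `cfg`.
#' @export
simulate_study <- function(cfg) {
  set.seed(cfg$seed)
  res_xy <- cbind(stats::runif(cfg$n_families, cfg$bbox[1], cfg$bbox[2]),
                  stats::runif(cfg$n_families, cfg$bbox[3], cfg$bbox[4]))
  soil <- simulate_soil(cfg, extra_xy = res_xy, reseed = FALSE)
  participants <- simulate_participants(cfg, res_xy, attr(soil, "extra_z"))
  list(soil = soil, participants = participants, canal = sim_canal(cfg),
       cfg = cfg)
}

#' Simulate exposure records with heteroscedastic Berkson error
#'
#' Direct generator for the measurement-error model: family-level assigned
#' exposures `x_pred`, per-family error SDs, latent true exposures
#' `x_true = x_pred + N(0, se^2)`, and outcomes from the random-intercept
#' regression on `x_true`. Used to study the Berkson fit in isolation.
#'
#' @param n_families,n_children Cohort sizes.
#' @param beta_soil True soil slope.
#' @param intercept True intercept.
#' @param family_sd,resid_sd Variance components (SD scale).
#' @param se_range Range of the uniform draw of per-family exposure SEs.
#' @param expo_range Range of assigned exposures (log10 mg/kg scale).
#' @param seed Optional seed.
#' @return An `"exposure_records"` data frame (`exposure_se` populated)
#'   with a `truth` attribute.
#' @export
simulate_berkson_records <- function(n_families = 64, n_children = 107,
                                     beta_soil = 0.3, intercept = -0.4,
                                     family_sd = sqrt(0.03),
                                     resid_sd = sqrt(0.06),
                                     se_range = c(0.05, 0.3),
                                     expo_range = c(-1, 1.6),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kids <- children_counts(n_families, n_children)
  fam <- c(seq_len(n_families), rep(seq_len(n_families), kids))
  np <- length(fam)
  x_pred_f <- stats::runif(n_families, expo_range[1], expo_range[2])
  se_f <- stats::runif(n_families, se_range[1], se_range[2])
  # Berkson noise independent per participant (co-located participants share
  # the assigned exposure and SE, not the latent deviation)
  x_true <- x_pred_f[fam] + stats::rnorm(np, sd = se_f[fam])
  b <- stats::rnorm(n_families, sd = family_sd)
  y <- intercept + beta_soil * x_true + b[fam] +
    stats::rnorm(np, sd = resid_sd)
  rec <- data.frame(id = sprintf("ID%03d", seq_len(np)),
                    family_id = sprintf("F%03d", fam),
                    outcome = y, exposure = x_pred_f[fam],
                    exposure_se = se_f[fam])
  attr(rec, "exposure_kind") <- "predicted"
  attr(rec, "outcome_kind") <- "urine"
  attr(rec, "truth") <- list(beta_soil = beta_soil, x_true = x_true,
                             family_sd = family_sd, resid_sd = resid_sd)
  class(rec) <- c("exposure_records", "data.frame")
  rec
}

#' Write a synthetic fixture suite to disk
#'
#' Emits the CSV/GeoJSON dialects consumed by the pipeline — soil table,
#' canal geometry, participant table — for a small and (optionally) a
#' full-scale configuration, plus a YAML manifest recording every seed and
#' all true generating parameters. Regeneration with the same seeds is
#' byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param scales Subset of `c("small", "full")`.
#' @param seed_small,seed_full Seeds for the two scales.
#' @return Named list of written file paths, invisibly.
#' @export
make_fixture_suite <- function(out_dir, scales = c("small", "full"),
                               seed_small = 101, seed_full = 202) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfgs <- list(
    small = sim_config(seed = seed_small, n_soil = 200, n_families = 20,
                       n_children = 33, extra_deep_frac = 0.15),
    full = sim_config(seed = seed_full))
  files <- list()
  manifest <- list()
  for (s in intersect(scales, names(cfgs))) {
    cfg <- cfgs[[s]]
    study <- simulate_study(cfg)
    soil_path <- file.path(out_dir, paste0("soil_", s, ".csv"))
    part_path <- file.path(out_dir, paste0("participants_", s, ".csv"))
    canal_path <- file.path(out_dir, paste0("canal_", s, ".geojson"))
    utils::write.csv(study$soil, soil_path, row.names = FALSE)
    utils::write.csv(study$participants, part_path, row.names = FALSE)
    write_canal_geojson(study$canal, canal_path)
    files[[s]] <- c(soil = soil_path, participants = part_path,
                    canal = canal_path)
    manifest[[s]] <- list(
      seed = cfg$seed, n_soil = cfg$n_soil, n_families = cfg$n_families,
      n_children = cfg$n_children, bbox = cfg$bbox,
      drift_beta = cfg$drift_beta,
      variogram = list(sill = cfg$vp$sigma2, nugget = cfg$vp$tau2,
                       range = cfg$vp$alpha, gamma = cfg$vp$gamma),
      lod = cfg$lod,
      urine_coef = as.list(cfg$urine_coef),
      hair_coef = as.list(cfg$hair_coef),
      urine_family_sd = cfg$urine_family_sd,
      urine_resid_sd = cfg$urine_resid_sd,
      hair_family_sd = cfg$hair_family_sd,
      hair_resid_sd = cfg$hair_resid_sd,
      files = as.list(basename(files[[s]])))
  }
  manifest_path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  files$manifest <- manifest_path
  invisible(files)
}

#' Read a soil sample CSV
#' @param path CSV with columns `x`, `y`, `hg_mgkg`, `depth_layer`,
#'   `parcel_id`, `below_lod`.
#' @return Data frame.
#' @export
read_soil_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "hg_mgkg", "depth_layer", "parcel_id", "below_lod")
  if (!all(need %in% names(df))) {
    stop("soil CSV must have columns: ", paste(need, collapse = ", "))
  }
  df$below_lod <- as.logical(df$below_lod)
  df
}

#' Read a participant CSV
#' @param path CSV with the participant columns (see
#'   [simulate_participants()] for the dialect).
#' @return Data frame.
#' @export
read_participants_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "family_id", "mother", "age", "x", "y", "urine_hg",
            "creatinine", "hair_hg", "amalgam_count", "seafish_portions_30d",
            "seafish_last3d", "smoking", "birth_country_near_sea",
            "eats_vegetables_region", "hair_dyeing_6m")
  if (!all(need %in% names(df))) {
    stop("participant CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  df
}
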