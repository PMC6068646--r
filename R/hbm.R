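#' Creatinine adjustment of urinary mercury
#'
#' Divides urinary mercury (ug/L) by urinary creatinine (g/L) to correct
#' for dilution. Samples with creatinine outside the WHO validity range
#' 0.3 to 3.0 g/L are excluded (returned as `NA` with the exclusion
#' flagged); the range is treated as closed, so the boundaries are kept.
#'
#' @param urine_ug_per_L Urinary mercury, ug/L (>= 0).
#' @param creatinine_g_per_L Urinary creatinine, g/L (>= 0).
#' @param range Validity range, default `c(0.3, 3.0)`.
#' @return Numeric vector of ug Hg / g creatinine, `NA` where excluded,
#'   with attribute `excluded` (logical vector).
#' @examples
#' creatinine_adjust(2, 0.5)    # 4 ug/g
#' creatinine_adjust(2, 0.25)   # excluded
#' @export
creatinine_adjust <- function(urine_ug_per_L, creatinine_g_per_L,
                              range = c(0.3, 3.0)) {
  stopifnot(all(urine_ug_per_L >= 0, na.rm = TRUE),
            all(creatinine_g_per_L >= 0, na.rm = TRUE))
  excluded <- is.na(creatinine_g_per_L) |
    creatinine_g_per_L < range[1] | creatinine_g_per_L > range[2]
  out <- ifelse(excluded, NA_real_, urine_ug_per_L / creatinine_g_per_L)
  attr(out, "excluded") <- excluded
  out
}

#' Substitute values below the limit of determination
#'
#' Soil mercury values below the limit of determination (default
#' 0.1 mg/kg) are set to half the limit; values at or above the limit are
#' kept. Idempotent.
#'
#' @param hg_mgkg Concentrations in mg/kg (>= 0).
#' @param lod Limit of determination, mg/kg.
#' @return Numeric vector with attribute `below_lod` (logical).
#' @examples
#' substitute_lod(c(0.08, 0.1, 44.0))
#' @export
substitute_lod <- function(hg_mgkg, lod = 0.1) {
  stopifnot(all(hg_mgkg >= 0, na.rm = TRUE), lod > 0)
  below <- !is.na(hg_mgkg) & hg_mgkg < lod
  out <- ifelse(below, lod / 2, hg_mgkg)
  attr(out, "below_lod") <- below
  out
}

#' Keep only topsoil samples
#'
#' Retains samples from the 0-20 cm layer, the layer humans are in contact
#' with. Emits a message with the retained count and a warning if nothing
#' remains.
#'
#' @param samples Data frame with a `depth_layer` column; topsoil rows are
#'   those whose label matches `topsoil_label`.
#' @param topsoil_label Default `"0-20"` (matched as a prefix, so
#'   `"0-20 cm"` also works).
#' @return The topsoil subset.
#' @export
filter_topsoil <- function(samples, topsoil_label = "0-20") {
  stopifnot("depth_layer" %in% names(samples))
  keep <- startsWith(as.character(samples$depth_layer), topsoil_label)
  out <- samples[keep, , drop = FALSE]
  message(sprintf("topsoil filter: retained %d of %d samples",
                  nrow(out), nrow(samples)))
  if (!nrow(out)) warning("no topsoil samples retained")
  out
}

hbm_covariate_sets <- list(
  urine = c("age", "mother", "amalgam_sqrt", "seafish_sqrt", "seafish_last3d",
            "smoking", "near_sea", "vegetables"),
  hair = c("age", "mother", "amalgam_sqrt", "seafish_sqrt",
           "smoking", "near_sea", "vegetables", "hair_dyeing"))

#' Encode questionnaire covariates for the outcome regressions
#'
#' Count covariates (amalgam fillings, sea-fish portions in the last 30
#' days) are square-root transformed; binary covariates become 0/1
#' indicators; age stays in years. The urine model set includes the
#' recent-sea-fish indicator (short-term urinary increase); the hair model
#' set drops it and adds the hair-dyeing indicator.
#'
#' @param participants Data frame with columns `id`, `family_id`, `mother`,
#'   `age`, `amalgam_count`, `seafish_portions_30d`, `seafish_last3d`,
#'   `smoking`, `birth_country_near_sea`, `eats_vegetables_region`,
#'   `hair_dyeing_6m`.
#' @param outcome_kind `"urine"` or `"hair"`.
#' @return Data frame of encoded covariates (plus `id`, `family_id`), one
#'   row per participant.
#' @export
encode_covariates <- function(participants, outcome_kind = c("urine", "hair")) {
  outcome_kind <- match.arg(outcome_kind)
  p <- participants
  if (any(p$amalgam_count < 0, na.rm = TRUE) ||
      any(p$seafish_portions_30d < 0, na.rm = TRUE)) {
    stop("counts must be non-negative")
  }
  enc <- data.frame(
    id = p$id, family_id = p$family_id,
    age = as.numeric(p$age),
    mother = as.numeric(p$mother),
    amalgam_sqrt = sqrt(p$amalgam_count),
    seafish_sqrt = sqrt(p$seafish_portions_30d),
    seafish_last3d = as.numeric(p$seafish_last3d),
    smoking = as.numeric(p$smoking),
    near_sea = as.numeric(p$birth_country_near_sea),
    vegetables = as.numeric(p$eats_vegetables_region),
    hair_dyeing = as.numeric(p$hair_dyeing_6m))
  enc[, c("id", "family_id", hbm_covariate_sets[[outcome_kind]])]
}

#' Assemble exposure records for the outcome regressions
#'
#' Links each participant to a soil exposure on the log10 scale:
#' `exposure = "measured"` uses the nearest soil sample on the
#' participant's parcel (falling back to the nearest sample overall when
#' the parcel has none and `fallback_nearest` is `TRUE`);
#' `exposure = "predicted"` kriges at the residence coordinates and also
#' carries the kriging standard error (`exposure_se`). Outcomes are log10
#' transformed; urine is creatinine-adjusted first and participants
#' outside the creatinine validity range are excluded. Participants with
#' missing covariates are dropped with a logged reason.
#'
#' @param participants Data frame (see [encode_covariates()]) with
#'   additional columns `x`, `y` (residence, meters), `urine_hg` (ug/L),
#'   `creatinine` (g/L), `hair_hg` (ug/g).
#' @param soil Soil sample data frame (`x`, `y`, `hg_mgkg`, `parcel_id`,
#'   `below_lod`), already topsoil-filtered and LOD-substituted. Required
#'   for `exposure = "measured"`.
#' @param model An [edkrige()] fit; required for `exposure = "predicted"`.
#' @param outcome_kind `"urine"` or `"hair"`.
#' @param exposure `"measured"` or `"predicted"`.
#' @param fallback_nearest Use the nearest sample overall when the parcel
#'   has no sample (default `TRUE`).
#' @return Data frame of class `"exposure_records"`: `id`, `family_id`,
#'   `outcome` (log10), encoded covariates, `exposure` (log10 mg/kg),
#'   `exposure_se` (0 for measured), `below_det_limit`; with an
#'   `exclusions` attribute (data frame `id`, `rule`).
#' @export
build_exposure_records <- function(participants, soil = NULL, model = NULL,
                                   outcome_kind = c("urine", "hair"),
                                   exposure = c("measured", "predicted"),
                                   fallback_nearest = TRUE) {
  outcome_kind <- match.arg(outcome_kind)
  exposure <- match.arg(exposure)
  p <- participants
  exclusions <- data.frame(id = character(0), rule = character(0))
  drop_rule <- function(ids, rule) {
    if (length(ids)) {
      exclusions <<- rbind(exclusions, data.frame(id = as.character(ids), rule = rule))
    }
  }

  if (outcome_kind == "urine") {
    adj <- creatinine_adjust(p$urine_hg, p$creatinine)
    drop_rule(p$id[attr(adj, "excluded")], "creatinine_out_of_range")
    outcome_raw <- as.numeric(adj)
  } else {
    outcome_raw <- p$hair_hg
  }
  bad <- is.na(outcome_raw) | outcome_raw <= 0
  drop_rule(p$id[bad & !(p$id %in% exclusions$id)], "missing_or_nonpositive_outcome")

  enc <- encode_covariates(p, outcome_kind)
  cov_missing <- !stats::complete.cases(enc)
  drop_rule(p$id[cov_missing & !(p$id %in% exclusions$id)], "missing_covariate")

  keep <- !bad & !cov_missing
  p <- p[keep, , drop = FALSE]
  enc <- enc[keep, , drop = FALSE]
  outcome <- log10(outcome_raw[keep])

  if (exposure == "measured") {
    if (is.null(soil)) stop("measured exposure needs the soil table")
    link <- link_nearest_sample(p, soil, fallback_nearest)
    expo <- log10(link$hg)
    expo_se <- rep(0, nrow(p))
    below <- link$below_lod
    no_link <- is.na(expo)
    drop_rule(p$id[no_link], "no_parcel_measurement")
    if (any(no_link)) {
      p <- p[!no_link, , drop = FALSE]; enc <- enc[!no_link, , drop = FALSE]
      outcome <- outcome[!no_link]; expo <- expo[!no_link]
      expo_se <- expo_se[!no_link]; below <- below[!no_link]
    }
  } else {
    if (is.null(model)) stop("predicted exposure needs a fitted kriging model")
    pr <- predict(model, p[, c("x", "y")])
    expo <- pr$mean
    expo_se <- pr$se
    below <- rep(FALSE, nrow(p))
  }

  out <- cbind(enc, data.frame(outcome = outcome, exposure = expo,
                               exposure_se = expo_se,
                               below_det_limit = as.numeric(below)))
  attr(out, "exclusions") <- exclusions
  attr(out, "outcome_kind") <- outcome_kind
  attr(out, "exposure_kind") <- exposure
  class(out) <- c("exposure_records", "data.frame")
  out
}

# nearest sample on the participant's parcel; optional global fallback
link_nearest_sample <- function(p, soil, fallback_nearest) {
  hg <- rep(NA_real_, nrow(p))
  below <- rep(NA, nrow(p))
  for (i in seq_len(nrow(p))) {
    cand <- if (!is.null(p$parcel_id)) which(soil$parcel_id == p$parcel_id[i]) else integer(0)
    if (!length(cand) && fallback_nearest) cand <- seq_len(nrow(soil))
    if (!length(cand)) next
    d2 <- (soil$x[cand] - p$x[i])^2 + (soil$y[cand] - p$y[i])^2
    j <- cand[which.min(d2)]
    hg[i] <- soil$hg_mgkg[j]
    below[i] <- isTRUE(as.logical(soil$below_lod[j]))
  }
  list(hg = hg, below_lod = below)
}
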