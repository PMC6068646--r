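test_that("creatinine adjustment divides and applies the validity range", {
  expect_equal(as.numeric(creatinine_adjust(2, 0.5)), 4)
  out <- creatinine_adjust(5, 0.25)
  expect_true(is.na(out))
  expect_true(attr(out, "excluded"))
  # closed interval: boundaries are kept
  expect_equal(as.numeric(creatinine_adjust(c(3, 6), c(0.3, 3.0))), c(10, 2))
  # zero creatinine is an exclusion, not a division error
  expect_true(is.na(creatinine_adjust(1, 0)))
  expect_error(creatinine_adjust(-1, 1))
})

test_that("LOD substitution halves values below the limit and is idempotent", {
  v <- substitute_lod(c(0.08, 0.1, 44.0))
  expect_equal(as.numeric(v), c(0.05, 0.1, 44.0))
  expect_equal(attr(v, "below_lod"), c(TRUE, FALSE, FALSE))
  again <- substitute_lod(as.numeric(v))
  expect_equal(as.numeric(again), as.numeric(v))
  expect_false(any(attr(again, "below_lod")[2:3]))
})

test_that("topsoil filter keeps only the 0-20 cm layer", {
  s <- data.frame(depth_layer = c("0-20 cm", "20-40 cm", "0-20 cm", "deeper",
                                  "0-20 cm"),
                  hg_mgkg = 1:5)
  expect_message(out <- filter_topsoil(s), "retained 3 of 5")
  expect_equal(out$hg_mgkg, c(1, 3, 5))
  all_top <- s[s$depth_layer == "0-20 cm", ]
  expect_message(expect_equal(nrow(filter_topsoil(all_top)), 3))
  none <- s[s$depth_layer == "deeper", ]
  expect_warning(suppressMessages(res <- filter_topsoil(none)), "no topsoil")
  expect_equal(nrow(res), 0)
})

make_participants <- function(n = 6) {
  data.frame(id = sprintf("P%02d", 1:n), family_id = rep(c("A", "B"), length.out = n),
             mother = rep(c(1, 0), length.out = n),
             age = c(30, 5, 40, 8, 35, 10)[1:n],
             x = seq(10, 10 * n, by = 10), y = rep(5, n),
             parcel_id = rep("P0000_0000", n),
             urine_hg = runif(n, 0.5, 3), creatinine = rep(1, n),
             hair_hg = runif(n, 0.1, 1),
             amalgam_count = c(4, 0, 2, 1, 0, 0)[1:n],
             seafish_portions_30d = c(0, 3, 1, 2, 4, 0)[1:n],
             seafish_last3d = rep(c(1, 0), length.out = n),
             smoking = rep(c(1, 0), length.out = n),
             birth_country_near_sea = rep(0, n),
             eats_vegetables_region = rep(1, n),
             hair_dyeing_6m = rep(c(1, 0), length.out = n))
}

test_that("covariate encoding square-roots counts and is outcome-specific", {
  p <- make_participants()
  eu <- encode_covariates(p, "urine")
  expect_equal(eu$amalgam_sqrt[1], 2)       # sqrt(4)
  expect_equal(eu$seafish_sqrt[1], 0)       # sqrt(0)
  expect_true("seafish_last3d" %in% names(eu))
  expect_false("hair_dyeing" %in% names(eu))
  eh <- encode_covariates(p, "hair")
  expect_true("hair_dyeing" %in% names(eh))
  expect_false("seafish_last3d" %in% names(eh))
  p$amalgam_count[1] <- -1
  expect_error(encode_covariates(p, "urine"), "non-negative")
})

test_that("encoding is deterministic and order-independent", {
  p <- make_participants()
  e1 <- encode_covariates(p, "urine")
  e2 <- encode_covariates(p[rev(seq_len(nrow(p))), ], "urine")
  expect_equal(e2[rev(seq_len(nrow(e2))), ], e1, ignore_attr = TRUE)
})

test_that("exposure records link measured soil and log exclusions", {
  set.seed(70)
  p <- make_participants()
  p$creatinine[3] <- 0.2    # out of range -> excluded from urine records
  soil <- data.frame(x = c(11, 100), y = c(5, 5), hg_mgkg = c(2, 0.05),
                     parcel_id = c("P0000_0000", "P0000_0000"),
                     below_lod = c(FALSE, TRUE))
  rec <- build_exposure_records(p, soil = soil, outcome_kind = "urine",
                                exposure = "measured")
  expect_equal(nrow(rec), 5)
  exc <- attr(rec, "exclusions")
  expect_true("creatinine_out_of_range" %in% exc$rule)
  expect_true(all(rec$exposure_se == 0))
  # nearest sample on the parcel: participant 1 at x=10 -> sample at x=11
  expect_equal(rec$exposure[rec$id == "P01"], log10(2))
  # hair records keep all participants (no creatinine rule)
  rech <- build_exposure_records(p, soil = soil, outcome_kind = "hair",
                                 exposure = "measured")
  expect_equal(nrow(rech), 6)
  expect_true("hair_dyeing" %in% names(rech))
})
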