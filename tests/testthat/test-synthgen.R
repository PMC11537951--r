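# small single-parameter config used by several tests
mini_config <- function(n_vols = 50, sigma_b = 3, sigma_e = 0.3,
                        sigma_r = 0, k = 2, rounding = FALSE) {
  synth_config(
    traits = tibble::tibble(parameter = "muac", age_group = "over12",
                            mu = 28, sigma_b = sigma_b),
    errors = tibble::tibble(rater_group = "fieldworker", parameter = "muac",
                            sigma_e = sigma_e, sigma_r = sigma_r),
    design = list(fieldworker = synth_design(
      n_volunteers = c(over12 = n_vols), n_raters = max(20, k + 1),
      k_prob = stats::setNames(1, as.character(k))
    )),
    rounding = rounding
  )
}

test_that("generation is deterministic given a seed and leaves RNG state alone", {
  a <- generate_dataset(mini_config(), seed = 123)
  b <- generate_dataset(mini_config(), seed = 123)
  expect_identical(a$records, b$records)
  c <- generate_dataset(mini_config(), seed = 124)
  expect_false(identical(a$records$value, c$records$value))

  withr::with_seed(1, {
    before <- runif(1)
  })
  generate_dataset(mini_config(), seed = 99)
  withr::with_seed(1, {
    expect_identical(runif(1), before)
  })
})

test_that("the noiseless limit yields constant replicates, TEM 0 and ICC 1", {
  sim <- generate_dataset(mini_config(sigma_e = 0, sigma_r = 0,
                                      rounding = FALSE), seed = 7)
  per_vol <- dplyr::summarise(
    dplyr::group_by(sim$records, volunteer_id),
    spread = diff(range(value)), .groups = "drop")
  expect_true(all(per_vol$spread == 0))
  v <- build_intra_view(sim$records, "muac", "fieldworker")
  expect_equal(pooled_tem(v), 0)
  expect_equal(icc_oneway(build_inter_view(sim$records, "muac",
                                           "fieldworker")), 1)
})

test_that("ground truth reports the variance-component implications", {
  cfg <- mini_config(sigma_b = 3, sigma_e = 0.3, sigma_r = 0.4)
  truth <- generate_dataset(cfg, seed = 5)$truth
  expect_equal(truth$tem_intra, 0.3)
  expect_equal(truth$tem_inter, sqrt(0.3^2 + 0.4^2), tolerance = 1e-12)
  expect_equal(truth$rho_inter, 9 / (9 + 0.16 + 0.09), tolerance = 1e-12)
  expect_equal(truth$rho_intra, (9 + 0.16) / (9 + 0.16 + 0.09),
               tolerance = 1e-12)
  expect_true(all(truth$rho_inter >= 0 & truth$rho_inter <= 1))
})

test_that("rater systematic bias creates the inter > intra TEM ordering", {
  sim <- generate_dataset(mini_config(n_vols = 300, sigma_e = 0.3,
                                      sigma_r = 0.5, k = 4), seed = 17)
  inter <- pooled_tem(build_inter_view(sim$records, "muac", "fieldworker"))
  intra <- pooled_tem(build_intra_view(sim$records, "muac", "fieldworker"))
  expect_gt(inter, intra)
})

test_that("instrument rounding inflates the observed TEM on paired draws", {
  # quantisation at 0.1 cm is material relative to sigma_e = 0.08
  rounded <- generate_dataset(mini_config(n_vols = 1000, sigma_e = 0.08,
                                          rounding = TRUE), seed = 29)
  raw <- generate_dataset(mini_config(n_vols = 1000, sigma_e = 0.08,
                                      rounding = FALSE), seed = 29)
  # same latent draws: rounding is the only difference
  expect_equal(
    round(raw$records$value / 0.1) * 0.1, rounded$records$value,
    tolerance = 1e-9)
  tem_rounded <- pooled_tem(build_intra_view(rounded$records, "muac",
                                             "fieldworker"))
  tem_raw <- pooled_tem(build_intra_view(raw$records, "muac",
                                         "fieldworker"))
  expect_gt(tem_rounded, tem_raw)
})

test_that("generated values sit on the instrument grid when rounding is on", {
  rec <- study_like_dataset(seed = 13)
  rep <- validate_measurements(rec)
  expect_equal(nrow(rep$off_grid), 0)
  expect_equal(nrow(rep$duplicates), 0)
})

test_that("the study-like preset matches the exercise design shape", {
  rec <- study_like_dataset(seed = 2)
  expect_s3_class(attr(rec, "truth"), "tbl_df")

  counts <- rec |>
    dplyr::distinct(rater_group, volunteer_id) |>
    dplyr::count(rater_group)
  expect_equal(counts$n[counts$rater_group == "site_lead"], 15)
  expect_equal(counts$n[counts$rater_group == "fieldworker"], 75)

  expect_lte(dplyr::n_distinct(
    rec$rater_id[rec$rater_group == "fieldworker"]), 46)
  expect_lte(dplyr::n_distinct(
    rec$rater_id[rec$rater_group == "site_lead"]), 12)

  # two rounds per (volunteer, rater, parameter)
  rounds <- rec |>
    dplyr::count(volunteer_id, rater_id, parameter, name = "n_rounds")
  expect_true(all(rounds$n_rounds == 2))

  # waist and calf restricted to the over-12 stratum
  wc <- add_age_group(rec) |>
    dplyr::filter(parameter %in% c("waist", "calf"))
  expect_true(all(wc$age_group == "over12"))

  # every inter-rater group within the 2-11 raters-per-volunteer design
  for (p in c("weight", "muac")) {
    ks <- dplyr::count(build_inter_view(rec, p, "fieldworker"), group_id)$n
    expect_true(all(ks >= 2 & ks <= 11))
  }
})

test_that("raters-per-volunteer distribution targets a median of 4", {
  p <- default_k_prob()
  counts <- as.integer(names(p))
  cum <- cumsum(p)
  expect_equal(counts[min(which(cum >= 0.5))], 4)
  expect_equal(min(counts), 2)
  expect_equal(max(counts), 11)
})
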