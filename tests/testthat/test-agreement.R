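# intra view with two rounds per pair, from vectors of r1 and r2 values
intra_view_from <- function(r1, r2) {
  n <- length(r1)
  tibble::tibble(
    group_id = rep(paste0("p", seq_len(n)), each = 2),
    value = as.vector(rbind(r1, r2)),
    round = rep(c(1L, 2L), n)
  )
}

test_that("intra-rater construction matches hand-computed bias and limits", {
  r1 <- c(10.0, 10.0, 10.0, 10.0)
  r2 <- c(10.2, 10.4, 10.0, 10.2) # differences 0.2, 0.4, 0.0, 0.2
  ba <- bland_altman_intra(intra_view_from(r1, r2))
  expect_equal(ba$bias, 0.2, tolerance = 1e-12)
  expect_equal(ba$sd_diff, sqrt(0.08 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_lower, 0.2 - 2 * sqrt(0.08 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_upper, 0.2 + 2 * sqrt(0.08 / 3), tolerance = 1e-12)
  expect_equal(round(c(ba$loa_lower, ba$loa_upper), 5),
               c(-0.12660, 0.52660))
  # CI contains the bias; x-axis is the pair mean
  expect_lte(ba$bias_ci_lower, ba$bias)
  expect_gte(ba$bias_ci_upper, ba$bias)
  expect_equal(ba$points$x, (r1 + r2) / 2)
})

test_that("degenerate difference sets produce warnings, not NaN limits", {
  expect_warning(
    ba <- bland_altman_intra(intra_view_from(c(10, 20, 30),
                                             c(10.2, 20.2, 30.2))),
    "degenerate"
  )
  expect_equal(c(ba$loa_lower, ba$loa_upper), c(0.2, 0.2))
  expect_equal(loa_coverage(ba), 1)

  expect_warning(
    perfect <- bland_altman_intra(intra_view_from(c(10, 20), c(10, 20))))
  expect_equal(perfect$bias, 0)
  expect_equal(c(perfect$loa_lower, perfect$loa_upper), c(0, 0))

  expect_warning(
    single <- bland_altman_intra(intra_view_from(10, 10.1)), "Fewer than 2")
  expect_true(is.na(single$bias))
})

test_that("swapping rounds flips the bias sign and keeps the limit width", {
  withr::with_seed(71, {
    r1 <- rnorm(40, 100, 5)
    r2 <- r1 + rnorm(40, 0.1, 0.3)
    v <- intra_view_from(r1, r2)
    a <- bland_altman_intra(v, sign = "r2_minus_r1")
    b <- bland_altman_intra(v, sign = "r1_minus_r2")
    expect_equal(a$bias, -b$bias, tolerance = 1e-12)
    expect_equal(a$loa_upper - a$loa_lower, b$loa_upper - b$loa_lower,
                 tolerance = 1e-12)
  })
})

test_that("inter-rater construction takes deviations from the volunteer mean", {
  v <- view_from_groups(list(A = c(10.0, 10.2, 10.4)))
  ba <- bland_altman_inter(v)
  expect_equal(sort(ba$points$y), c(-0.2, 0, 0.2), tolerance = 1e-12)
  expect_equal(ba$points$x, rep(10.2, 3), tolerance = 1e-12)
  expect_equal(ba$bias, 0, tolerance = 1e-12)
})

test_that("inter-rater bias is structurally zero for any input", {
  withr::with_seed(81, {
    for (i in 1:10) {
      v <- random_view(n_groups = sample(3:15, 1), k_range = 2:6)
      ba <- bland_altman_inter(v)
      expect_lt(abs(ba$bias), 1e-10)
      # per-volunteer deviations sum to zero
      sums <- tapply(ba$points$y, ba$points$group_id, sum)
      expect_true(all(abs(sums) < 1e-10))
    }
  })
})

test_that("coverage is recomputed from stored points and LoA", {
  withr::with_seed(91, {
    r1 <- rnorm(200, 50, 3)
    r2 <- r1 + rnorm(200, 0, 0.4)
    ba <- bland_altman_intra(intra_view_from(r1, r2))
    manual <- mean(ba$points$y >= ba$loa_lower & ba$points$y <= ba$loa_upper)
    expect_equal(loa_coverage(ba), manual)
    expect_equal(ba$prop_within_loa, manual)
    expect_gt(manual, 0.9)
  })
})

test_that("the LoA multiplier is configurable", {
  withr::with_seed(101, {
    v <- intra_view_from(rnorm(50, 50, 3), rnorm(50, 50, 3))
    ba2 <- bland_altman_intra(v, multiplier = 2)
    ba196 <- bland_altman_intra(v, multiplier = 1.96)
    expect_equal(ba196$loa_upper - ba196$loa_lower,
                 (1.96 / 2) * (ba2$loa_upper - ba2$loa_lower),
                 tolerance = 1e-12)
  })
})

test_that("tidy, glance and the point export expose the analysis", {
  withr::with_seed(111, {
    v <- intra_view_from(rnorm(30, 50, 3), rnorm(30, 50.1, 3))
    ba <- bland_altman_intra(v)
    expect_equal(nrow(tidy(ba)), 30)
    g <- glance(ba)
    expect_equal(g$n_points, 30)
    expect_equal(g$loa_upper, ba$loa_upper)
    path <- withr::local_tempfile(fileext = ".csv")
    write_bland_altman(ba, path)
    back <- readr::read_csv(path, show_col_types = FALSE)
    expect_equal(back$y, ba$points$y)
    p <- autoplot(ba)
    expect_s3_class(p, "ggplot")
  })
})
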