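test_that("pooled TEM matches hand-computed duplicate and multi-rater cases", {
  # four pairs with differences 0.1, -0.1, 0.2, 0.0: sqrt(0.06 / 8)
  pairs <- view_from_groups(list(c(10.0, 10.1), c(10.0, 9.9),
                                 c(10.0, 10.2), c(10.0, 10.0)))
  expect_equal(pooled_tem(pairs), sqrt(0.06 / 8), tolerance = 1e-12)

  # unbalanced: within-group SS 0.08 and 0.06, denominator (3-1) + (3-1)
  multi <- view_from_groups(list(c(10.0, 10.2, 10.4), c(20.0, 20.0, 20.3)))
  expect_equal(pooled_tem(multi), sqrt((0.08 + 0.06) / 4), tolerance = 1e-12)

  # zero within-group variance
  flat <- view_from_groups(list(c(5, 5), c(7, 7, 7)))
  expect_equal(pooled_tem(flat), 0)
})

test_that("pooled TEM rejects under-replicated groups and flags empty sets", {
  expect_error(pooled_tem(view_from_groups(list(c(1, 2), 3))), "at least 2")
  empty <- tibble::tibble(group_id = character(), value = double())
  expect_warning(out <- pooled_tem(empty), "undefined")
  expect_true(is.na(out))
})

test_that("TEM is scale-equivariant and shift-invariant; %TEM and R are scale-invariant", {
  withr::with_seed(21, {
    for (i in 1:20) {
      v <- random_view(n_groups = sample(2:8, 1))
      tem <- pooled_tem(v)
      scaled <- dplyr::mutate(v, value = value * 3.7)
      shifted <- dplyr::mutate(v, value = value + 11.3)
      expect_equal(pooled_tem(scaled), 3.7 * tem, tolerance = 1e-12)
      expect_equal(pooled_tem(shifted), tem, tolerance = 1e-9)
      expect_equal(relative_tem(3.7 * tem, 3.7 * mean(v$value)),
                   relative_tem(tem, mean(v$value)), tolerance = 1e-12)
      expect_equal(
        suppressWarnings(coefficient_of_reliability(3.7 * tem,
                                                    3.7 * sd(v$value))),
        suppressWarnings(coefficient_of_reliability(tem, sd(v$value))),
        tolerance = 1e-12)
      # %TEM is *not* shift-invariant: comparisons require similar means
      expect_false(isTRUE(all.equal(relative_tem(tem, mean(v$value) + 50),
                                    relative_tem(tem, mean(v$value)))))
    }
  })
})

test_that("relative TEM applies the percentage formula and guards its domain", {
  expect_equal(relative_tem(0.5, 25), 2)
  expect_equal(relative_tem(0, 10), 0)
  expect_error(relative_tem(0.5, 0), "positive")
  expect_error(relative_tem(0.5, -1), "positive")
})

test_that("coefficient of reliability follows 1 - TEM^2/SD^2 with flagged edge cases", {
  expect_equal(coefficient_of_reliability(0.1, 1), 0.99)
  expect_equal(coefficient_of_reliability(0, 2), 1)
  expect_equal(coefficient_of_reliability(1.5, 1.5), 0)
  expect_warning(r <- coefficient_of_reliability(0.5, 0), "undefined")
  expect_true(is.na(r))
  expect_warning(neg <- coefficient_of_reliability(2, 1), "Negative")
  expect_equal(neg, -3)
})

test_that("TEM F comparison matches the squared-ratio definition", {
  cmp <- compare_tem(0.097, 48, 0.291, 321)
  expect_equal(cmp$f_stat, (0.097 / 0.291)^2, tolerance = 1e-12)
  expect_equal(cmp$f_stat, 1 / 9, tolerance = 1e-12) # 0.097/0.291 is exactly 1/3
  expect_equal(cmp$df1, 47)
  expect_equal(cmp$df2, 320)
  expect_lt(cmp$p_value, 0.05)

  null <- compare_tem(0.2, 10, 0.2, 10)
  expect_equal(null$f_stat, 1)
  expect_equal(null$p_value, 1)
  expect_equal(compare_tem(0.2, 10, 0.1, 15)$f_stat, 4)

  # two-sided p is symmetric in the group order
  a <- compare_tem(0.3, 20, 0.5, 30)
  b <- compare_tem(0.5, 30, 0.3, 20)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)

  expect_warning(und <- compare_tem(0.2, 10, 0, 10), "undefined")
  expect_true(is.na(und$p_value))
})

test_that("threshold classification reproduces the published rule outcomes", {
  res <- tibble::tibble(
    parameter = c("weight", "muac", "length_height"),
    mode = c("inter", "inter", "intra"),
    pct_tem = c(0.923, 3.0, 1.2),
    icc = c(0.999, 0.851, 0.99),
    r_coef = c(0.999, 0.881, 0.99)
  )
  cls <- classify_reliability(res, built_in_thresholds())

  # weight inter %TEM 0.923 passes the < 2.0 benchmark
  carsley_weight <- dplyr::filter(cls, set == "carsley2019",
                                  parameter == "weight")
  expect_true(all(carsley_weight$pass))

  # ICC 0.851 fails the > 0.90 "excellent" bar
  icc_muac <- dplyr::filter(cls, rule == "icc_gt_0.9", parameter == "muac")
  expect_false(icc_muac$pass)

  # intra %TEM 1.2: fails the experienced (< 1.0), passes the beginner (< 1.5)
  expect_false(dplyr::filter(cls, set == "perini_experienced",
                             parameter == "length_height")$pass)
  expect_true(dplyr::filter(cls, set == "perini_beginner",
                            parameter == "length_height")$pass)

  # MUAC is out of scope for the %TEM rules: no carsley row for it
  expect_equal(nrow(dplyr::filter(cls, set == "carsley2019",
                                  parameter == "muac")), 0)
})

test_that("rules referencing a missing statistic are reported as not evaluable", {
  res <- tibble::tibble(parameter = "weight", mode = "inter",
                        pct_tem = 1.0, icc = NA_real_, r_coef = 0.99)
  cls <- classify_reliability(res, built_in_thresholds("icc_excellent"))
  expect_true(is.na(dplyr::filter(cls, rule == "icc_gt_0.9")$pass))
  expect_true(dplyr::filter(cls, rule == "r_gt_0.9")$pass)
})

test_that("threshold sets round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    list(set = "custom", rule = "tight_muac", statistic = "pct_tem",
         mode = "inter", op = "<", cutoff = 1.2,
         parameters = list("muac"))
  ), path)
  th <- read_thresholds(path)
  expect_equal(th$cutoff, 1.2)
  expect_equal(th$parameters[[1]], "muac")
  res <- tibble::tibble(parameter = "muac", mode = "inter", pct_tem = 1.1)
  expect_true(classify_reliability(res, th)$pass)
})
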