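#' Pooled technical error of measurement
#'
#' The technical error of measurement (TEM) is the standard deviation of
#' replicate measurements of the same unchanged subject, pooled over
#' subjects, in the units of the measurement. For replicate groups
#' \eqn{i = 1, \dots, N} with \eqn{k_i} measurements \eqn{x_{ij}} each,
#'
#' \deqn{TEM = \sqrt{\frac{\sum_i \sum_j (x_{ij} - \bar x_i)^2}
#'                        {\sum_i (k_i - 1)}}}
#'
#' the square root of the one-way within-group mean square. With duplicate
#' measurements throughout (\eqn{k_i = 2}) this reduces exactly to the
#' classical \eqn{\sqrt{\sum_i d_i^2 / 2N}} on the pair differences
#' \eqn{d_i}; with balanced \eqn{k_i = k} it reduces to the classical
#' multi-rater formula. The pooled form handles unbalanced designs (2-11
#' raters per volunteer) with no further assumptions.
#'
#' @param view A replicate view ([build_inter_view()] /
#'   [build_intra_view()]), or any data frame with `group_id` and `value`
#'   columns. Every group must have at least two values; build the view
#'   first so under-replicated groups have been excluded.
#'
#' @return A single non-negative number, or `NA` (with a warning) for an
#'   empty view.
#' @examples
#' pairs <- tibble::tibble(
#'   group_id = rep(letters[1:4], each = 2),
#'   value = c(10, 10.1, 10, 9.9, 10, 10.2, 10, 10)
#' )
#' pooled_tem(pairs) # sqrt(sum(d^2) / (2 * 4))
#' @export
pooled_tem <- function(view) {
  stopifnot(is.data.frame(view), all(c("group_id", "value") %in% names(view)))
  if (nrow(view) == 0) {
    warn("Empty replicate set: TEM is undefined (NA).")
    return(NA_real_)
  }
  gs <- group_stats(view)
  if (any(gs$k < 2)) {
    abort("Every replicate group must have at least 2 values; filter under-replicated groups first (build_inter_view does this).")
  }
  sqrt(sum(gs$ss) / sum(gs$k - 1))
}

#' Relative technical error of measurement
#'
#' Expresses the TEM as a percentage of the mean measurement,
#' \eqn{\%TEM = 100 \cdot TEM / \bar x}, compensating for the correlation
#' between TEM and measurement size so that parameters of different
#' magnitudes (infant weight vs adult height) can be compared on one scale.
#'
#' @param tem Non-negative TEM in measurement units.
#' @param grand_mean Positive mean of the measurements the TEM was computed
#'   from.
#' @return Percentage (e.g. `2.0` for 2%).
#' @examples
#' relative_tem(0.5, 25) # 2
#' @export
relative_tem <- function(tem, grand_mean) {
  if (any(!is.na(grand_mean) & grand_mean <= 0)) {
    abort("`grand_mean` must be positive.")
  }
  100 * tem / grand_mean
}

#' Coefficient of reliability
#'
#' \eqn{R = 1 - TEM^2 / SD^2}: the proportion of the observed between-subject
#' variance not attributable to measurement error, where `SD` is the standard
#' deviation of the measurements in the stratum. \eqn{R} can be negative when
#' the measurement error exceeds the between-subject spread; such values are
#' returned as computed (with a warning) rather than truncated at zero, since
#' truncation would hide pathological strata.
#'
#' @param tem Non-negative TEM.
#' @param between_subject_sd Positive standard deviation of the measurements.
#' @return A number \eqn{\le 1}, or `NA` with a warning when
#'   `between_subject_sd` is zero.
#' @examples
#' coefficient_of_reliability(0.1, 1) # 0.99
#' @export
coefficient_of_reliability <- function(tem, between_subject_sd) {
  if (any(!is.na(between_subject_sd) & between_subject_sd < 0)) {
    abort("`between_subject_sd` must be non-negative.")
  }
  out <- ifelse(
    is.na(between_subject_sd) | between_subject_sd == 0,
    NA_real_,
    1 - tem^2 / between_subject_sd^2
  )
  if (any(!is.na(between_subject_sd) & between_subject_sd == 0)) {
    warn("Zero between-subject SD: R is undefined (NA).")
  }
  if (any(!is.na(out) & out < 0)) {
    warn("Negative coefficient of reliability: measurement error exceeds between-subject spread.")
  }
  out
}

#' Per-stratum TEM summary
#'
#' Computes the TEM family for one replicate view: observation count `n`
#' (\eqn{\sum_i k_i}), number of replicate groups, grand mean, between-subject
#' SD (the SD of all observations in the view), `tem`, `pct_tem` and
#' `r_coef`. The identities `pct_tem == 100 * tem / grand_mean` and
#' `r_coef == 1 - tem^2 / between_sd^2` hold exactly in the returned row.
#'
#' @inheritParams pooled_tem
#' @return A one-row tibble. All statistics are `NA` for an empty view.
#' @export
tem_summary <- function(view) {
  stopifnot(is.data.frame(view), all(c("group_id", "value") %in% names(view)))
  if (nrow(view) == 0) {
    return(tibble::tibble(
      n = 0L, n_groups = 0L, grand_mean = NA_real_, between_sd = NA_real_,
      tem = NA_real_, pct_tem = NA_real_, r_coef = NA_real_
    ))
  }
  tem <- pooled_tem(view)
  grand_mean <- mean(view$value)
  between_sd <- stats::sd(view$value)
  tibble::tibble(
    n = nrow(view),
    n_groups = dplyr::n_distinct(view$group_id),
    grand_mean = grand_mean,
    between_sd = between_sd,
    tem = tem,
    pct_tem = relative_tem(tem, grand_mean),
    r_coef = coefficient_of_reliability(tem, between_sd)
  )
}

#' Compare two TEMs with an F statistic
#'
#' Tests whether two rater groups (e.g. site leads vs fieldworkers) achieve
#' different measurement error, using \eqn{F = TEM_a^2 / TEM_b^2} referred to
#' an F distribution on \eqn{(n_a - 1, n_b - 1)} degrees of freedom, where
#' `n` is the observation count of each group's replicate set. The p-value is
#' two-sided: \eqn{p = \min(1, 2\min(P(F \le f), P(F \ge f)))}, symmetric in
#' the group order.
#'
#' The `df1` / `df2` arguments override the default `n - 1` convention; the
#' exact chi-square degrees of freedom of a pooled TEM are
#' \eqn{\sum_i (k_i - 1)}, which equals `n - 1` only when the replicate set
#' is a single group, so calibrated inference on multi-group sets should pass
#' the pooled within-group degrees of freedom explicitly.
#'
#' @param tem_a,tem_b Positive TEMs to compare.
#' @param n_a,n_b Observation counts (\eqn{\ge 2}) behind each TEM.
#' @param df1,df2 Degrees of freedom; default `n_a - 1` and `n_b - 1`.
#' @return A one-row tibble: `f_stat`, `df1`, `df2`, `p_value`, `tem_a`,
#'   `tem_b`, `direction` (which TEM is smaller). `NA` statistics, with a
#'   warning, when `tem_b` is zero.
#' @examples
#' compare_tem(0.097, 48, 0.291, 321) # site leads vs fieldworkers
#' @export
compare_tem <- function(tem_a, n_a, tem_b, n_b,
                        df1 = n_a - 1, df2 = n_b - 1) {
  stopifnot(length(tem_a) == 1, length(tem_b) == 1)
  if (is.na(tem_a) || is.na(tem_b) || tem_b == 0) {
    if (!is.na(tem_b) && tem_b == 0) {
      warn("Zero reference TEM: F comparison is undefined (NA).")
    }
    return(tibble::tibble(
      f_stat = NA_real_, df1 = NA_real_, df2 = NA_real_, p_value = NA_real_,
      tem_a = tem_a, tem_b = tem_b, direction = NA_character_
    ))
  }
  stopifnot(n_a >= 2, n_b >= 2, tem_a > 0)
  f <- (tem_a / tem_b)^2
  p <- min(1, 2 * min(pf(f, df1, df2), pf(f, df1, df2, lower.tail = FALSE)))
  tibble::tibble(
    f_stat = f, df1 = df1, df2 = df2, p_value = p,
    tem_a = tem_a, tem_b = tem_b,
    direction = dplyr::case_when(
      tem_a < tem_b ~ "a_smaller",
      tem_a > tem_b ~ "b_smaller",
      TRUE ~ "equal"
    )
  )
}
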