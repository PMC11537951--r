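#' Assign volunteers to age groups
#'
#' Maps age in years onto the three survey age strata: infants and toddlers
#' (`under2`), children (`two_to_12`) and adolescents/adults (`over12`).
#' The band labels "0 <= 2", "2-12" and ">12" overlap at 2 years and are
#' ambiguous at 12, so the package fixes one total convention:
#' \eqn{[0, b_1) \rightarrow} `under2`, \eqn{[b_1, b_2] \rightarrow}
#' `two_to_12`, \eqn{(b_2, \infty) \rightarrow} `over12`, with default
#' breaks \eqn{b_1 = 2}, \eqn{b_2 = 12}. This keeps ">12" literal and sends
#' exact second birthdays to the older group. The breaks are configurable for
#' sensitivity analyses.
#'
#' @param age_years Numeric vector of non-negative ages in years.
#' @param breaks Numeric length-2 vector `c(b1, b2)` with `0 < b1 < b2`.
#'
#' @return A factor with levels `under2`, `two_to_12`, `over12`, same length
#'   as `age_years`. `NA` ages map to `NA`.
#' @examples
#' assign_age_group(c(0.8, 2, 12, 12.01))
#' @export
assign_age_group <- function(age_years, breaks = c(2, 12)) {
  stopifnot(is.numeric(age_years), length(breaks) == 2, breaks[1] > 0,
            breaks[1] < breaks[2])
  if (any(age_years < 0, na.rm = TRUE)) {
    abort("`age_years` must be non-negative.")
  }
  out <- dplyr::case_when(
    is.na(age_years) ~ NA_character_,
    age_years < breaks[1] ~ "under2",
    age_years <= breaks[2] ~ "two_to_12",
    TRUE ~ "over12"
  )
  factor(out, levels = tem_age_groups())
}

#' Add an `age_group` column to a measurement table
#'
#' Pipe-friendly wrapper around [assign_age_group()]: adds (or overwrites)
#' the `age_group` column derived from `age_years`.
#'
#' @param records A measurement tibble with an `age_years` column.
#' @inheritParams assign_age_group
#' @return `records` with an `age_group` factor column.
#' @export
add_age_group <- function(records, breaks = c(2, 12)) {
  if (!"age_years" %in% names(records)) {
    abort("`records` must have an `age_years` column.")
  }
  dplyr::mutate(records, age_group = assign_age_group(.data$age_years, breaks))
}
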