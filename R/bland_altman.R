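#' Bland-Altman agreement analysis
#'
#' Two constructions quantify measurement agreement as used in
#' standardisation exercises:
#'
#' * **Intra-rater** ([bland_altman_intra()]): for each (volunteer, rater)
#'   pair, the difference between the two rounds (y-axis, default
#'   `round2 - round1`) against their mean (x-axis).
#' * **Inter-rater** ([bland_altman_inter()]): for each volunteer and each of
#'   their raters, the difference between that rater's first measurement and
#'   the mean of all included first-round measurements of the volunteer
#'   (y-axis) against that mean (x-axis). Deviations from a group's own mean
#'   sum to zero within each volunteer, so the overall bias of this
#'   construction is structurally zero (up to floating point) — the
#'   informative quantities are the spread and the limits of agreement.
#'
#' The bias is the mean of the differences, with a t-based
#' \eqn{100(1-\alpha)\%} confidence interval
#' \eqn{\bar y \pm t_{1-\alpha/2, n-1}\, s_y/\sqrt n}. The limits of
#' agreement are `bias ± multiplier * sd_diff` with multiplier 2 by default
#' (configurable, e.g. 1.96). When all differences are equal the limits
#' degenerate to a point and a warning is attached instead of producing
#' `NaN`.
#'
#' @param view An intra-rater or inter-rater replicate view (see
#'   [build_intra_view()], [build_inter_view()]).
#' @param sign For the intra construction, `"r2_minus_r1"` (default) or
#'   `"r1_minus_r2"`; swapping rounds flips the bias sign and leaves the
#'   width of the limits unchanged.
#' @param multiplier Width of the limits of agreement in SDs of the
#'   differences (default 2).
#' @param conf_level Confidence level of the bias interval (default 0.95).
#' @param reference_records For the inter construction only: optionally a
#'   full measurement table from which the per-volunteer reference mean is
#'   computed over *both* rounds instead of the default first-round-only
#'   mean. The plotted first-round points are unchanged.
#'
#' @return A `bland_altman` object: list with `points` (tibble of `x`, `y`
#'   and identifiers), `n_points`, `bias`, `bias_ci_lower/upper`, `sd_diff`,
#'   `loa_lower/upper`, `prop_within_loa`, `mode`, `multiplier`,
#'   `conf_level`, `notes`. Fewer than 2 points gives `NA` statistics with a
#'   warning. Methods: [tidy()] (points), [glance()] (one-row statistics),
#'   [autoplot()] (ggplot), `print()`.
#' @examples
#' rec <- study_like_dataset(seed = 1)
#' ba <- build_intra_view(rec, "weight", "fieldworker") |> bland_altman_intra()
#' glance(ba)
#' @name bland_altman
NULL

new_bland_altman <- function(points, mode, multiplier, conf_level) {
  n <- nrow(points)
  notes <- character()
  if (n < 2) {
    warn("Fewer than 2 difference points: Bland-Altman statistics are undefined (NA).")
    stats <- list(bias = NA_real_, bias_ci_lower = NA_real_,
                  bias_ci_upper = NA_real_, sd_diff = NA_real_,
                  loa_lower = NA_real_, loa_upper = NA_real_,
                  prop_within_loa = NA_real_)
    notes <- "undefined: fewer than 2 points"
  } else {
    bias <- mean(points$y)
    sd_diff <- stats::sd(points$y)
    if (sd_diff == 0) {
      warn("All differences identical: limits of agreement degenerate to the bias.")
      notes <- "degenerate: zero SD of differences"
      ci <- c(bias, bias)
    } else {
      half <- qt(1 - (1 - conf_level) / 2, df = n - 1) * sd_diff / sqrt(n)
      ci <- c(bias - half, bias + half)
    }
    loa <- c(bias - multiplier * sd_diff, bias + multiplier * sd_diff)
    stats <- list(
      bias = bias, bias_ci_lower = ci[1], bias_ci_upper = ci[2],
      sd_diff = sd_diff, loa_lower = loa[1], loa_upper = loa[2],
      prop_within_loa = mean(points$y >= loa[1] & points$y <= loa[2])
    )
  }
  structure(
    c(list(points = points, n_points = n, mode = mode,
           multiplier = multiplier, conf_level = conf_level, notes = notes),
      stats),
    class = "bland_altman"
  )
}

#' @rdname bland_altman
#' @export
bland_altman_intra <- function(view, sign = c("r2_minus_r1", "r1_minus_r2"),
                               multiplier = 2, conf_level = 0.95) {
  sign <- match.arg(sign)
  stopifnot(is.data.frame(view),
            all(c("group_id", "value", "round") %in% names(view)))
  wide <- view |>
    tibble::as_tibble() |>
    dplyr::select("group_id", "round", "value") |>
    tidyr::pivot_wider(names_from = "round", values_from = "value",
                       names_prefix = "r") |>
    dplyr::filter(!is.na(.data$r1), !is.na(.data$r2))
  points <- tibble::tibble(
    group_id = wide$group_id,
    x = (wide$r1 + wide$r2) / 2,
    y = if (sign == "r2_minus_r1") wide$r2 - wide$r1 else wide$r1 - wide$r2
  )
  new_bland_altman(points, mode = "intra", multiplier = multiplier,
                   conf_level = conf_level)
}

#' @rdname bland_altman
#' @export
bland_altman_inter <- function(view, multiplier = 2, conf_level = 0.95,
                               reference_records = NULL) {
  stopifnot(is.data.frame(view),
            all(c("group_id", "value") %in% names(view)))
  if (is.null(reference_records)) {
    refs <- view |>
      dplyr::group_by(.data$group_id) |>
      dplyr::summarise(ref = mean(.data$value), .groups = "drop")
  } else {
    # reference mean over both rounds of the included volunteers
    refs <- reference_records |>
      dplyr::filter(.data$parameter == attr(view, "parameter"),
                    .data$volunteer_id %in% unique(view$group_id)) |>
      dplyr::group_by(group_id = .data$volunteer_id) |>
      dplyr::summarise(ref = mean(.data$value), .groups = "drop")
  }
  pts <- view |>
    tibble::as_tibble() |>
    dplyr::inner_join(refs, by = "group_id")
  points <- tibble::tibble(
    group_id = pts$group_id,
    rater_id = if ("rater_id" %in% names(pts)) pts$rater_id else NA_character_,
    x = pts$ref,
    y = pts$value - pts$ref
  )
  new_bland_altman(points, mode = "inter", multiplier = multiplier,
                   conf_level = conf_level)
}

#' Proportion of points within the limits of agreement
#'
#' Fraction of the stored difference points `y` with
#' `loa_lower <= y <= loa_upper`. Recomputed from the points, not read from
#' a cached field.
#'
#' @param result A `bland_altman` object.
#' @return A number in \[0, 1\].
#' @export
loa_coverage <- function(result) {
  stopifnot(inherits(result, "bland_altman"))
  if (result$n_points < 1 || is.na(result$loa_lower)) return(NA_real_)
  mean(result$points$y >= result$loa_lower &
         result$points$y <= result$loa_upper)
}

#' @export
print.bland_altman <- function(x, digits = 3, ...) {
  cat("Bland-Altman agreement (", x$mode, "-rater construction)\n", sep = "")
  cat("  points:", x$n_points, "\n")
  cat("  bias:  ", format(round(x$bias, digits), nsmall = digits),
      " [", format(round(x$bias_ci_lower, digits), nsmall = digits), ", ",
      format(round(x$bias_ci_upper, digits), nsmall = digits), "] (",
      round(100 * x$conf_level), "% CI)\n", sep = "")
  cat("  SD of differences:", format(round(x$sd_diff, digits), nsmall = digits), "\n")
  cat("  limits of agreement (", x$multiplier, " SD): [",
      format(round(x$loa_lower, digits), nsmall = digits), ", ",
      format(round(x$loa_upper, digits), nsmall = digits), "]\n", sep = "")
  if (!is.na(x$prop_within_loa)) {
    cat("  within limits:", sprintf("%.1f%%", 100 * x$prop_within_loa), "\n")
  }
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) {
  x$points
}

#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(
    mode = x$mode, n_points = x$n_points, bias = x$bias,
    bias_ci_lower = x$bias_ci_lower, bias_ci_upper = x$bias_ci_upper,
    sd_diff = x$sd_diff, loa_lower = x$loa_lower, loa_upper = x$loa_upper,
    prop_within_loa = x$prop_within_loa, multiplier = x$multiplier,
    conf_level = x$conf_level
  )
}

#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  stopifnot(object$n_points >= 1)
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$bias_ci_lower, ymax = object$bias_ci_upper,
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = if (object$mode == "intra") "Mean of the two rounds" else
        "Mean of first-round measurements",
      y = "Difference",
      title = paste0("Bland-Altman (", object$mode, "-rater)"),
      subtitle = sprintf("bias %.3f, limits of agreement [%.3f, %.3f]",
                         object$bias, object$loa_lower, object$loa_upper)
    ) +
    ggplot2::theme_minimal()
}

#' Export Bland-Altman points to CSV
#'
#' Writes the (x, y) difference points for external plotting.
#'
#' @param result A `bland_altman` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_bland_altman <- function(result, path) {
  stopifnot(inherits(result, "bland_altman"))
  readr::write_csv(result$points, path)
  invisible(path)
}
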