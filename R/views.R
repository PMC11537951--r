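#' Replicate views: the common input to TEM and ICC
#'
#' Reliability statistics operate on sets of replicate measurements of an
#' unchanged subject. Two views of a measurement table provide them:
#'
#' * **inter-rater** ([build_inter_view()]): one replicate group per
#'   volunteer, containing each rater's *first-round* measurement. Volunteers
#'   measured by fewer than two distinct raters are excluded (no between-rater
#'   information) and recorded in the `excluded_volunteers` attribute.
#' * **intra-rater** ([build_intra_view()]): one replicate group per
#'   (volunteer, rater) pair, containing that rater's round-1 and round-2
#'   measurements. Pairs missing a round are dropped and recorded in the
#'   `dropped_pairs` attribute.
#'
#' A view is a tibble with columns `group_id`, `value` plus the identifying
#' columns, carrying attributes `mode`, `parameter` and `stratum`. The
#' observation count `n` reported downstream is `nrow(view)`, i.e.
#' \eqn{\sum_i k_i} over replicate groups.
#'
#' @param records A measurement tibble (see [read_measurements()]). An
#'   `age_group` column is derived from `age_years` if absent.
#' @param parameter One of [tem_parameters()].
#' @param rater_group Optional: restrict to one of [tem_rater_groups()].
#' @param age_group Optional: restrict to one of [tem_age_groups()].
#'
#' @return A `replicate_view` tibble (possibly with zero rows, which
#'   downstream statistics translate into `NA` markers rather than errors).
#' @examples
#' rec <- study_like_dataset(seed = 1)
#' v <- build_inter_view(rec, "weight", rater_group = "fieldworker")
#' dplyr::count(v, group_id) |> head()
#' @name replicate_views
NULL

new_replicate_view <- function(data, mode, parameter, stratum, extra = list()) {
  out <- tibble::as_tibble(data)
  attr(out, "mode") <- mode
  attr(out, "parameter") <- parameter
  attr(out, "stratum") <- stratum
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("replicate_view", class(out))
  out
}

view_mode <- function(view) attr(view, "mode")

filter_stratum <- function(records, parameter, rater_group, age_group) {
  check_parameter(parameter)
  if (!"age_group" %in% names(records)) records <- add_age_group(records)
  out <- dplyr::filter(records, .data$parameter == !!parameter)
  if (!is.null(rater_group)) {
    check_rater_group(rater_group)
    out <- dplyr::filter(out, .data$rater_group == !!rater_group)
  }
  if (!is.null(age_group)) {
    stopifnot(age_group %in% tem_age_groups())
    out <- dplyr::filter(out, .data$age_group == !!age_group)
  }
  out
}

#' @rdname replicate_views
#' @export
build_inter_view <- function(records, parameter, rater_group = NULL,
                             age_group = NULL) {
  sub <- filter_stratum(records, parameter, rater_group, age_group) |>
    dplyr::filter(.data$round == 1L)

  rater_counts <- sub |>
    dplyr::distinct(.data$volunteer_id, .data$rater_id) |>
    dplyr::count(.data$volunteer_id, name = "n_raters")
  excluded <- rater_counts$volunteer_id[rater_counts$n_raters < 2]

  kept <- sub |>
    dplyr::filter(!.data$volunteer_id %in% excluded) |>
    dplyr::transmute(
      group_id = .data$volunteer_id,
      value = .data$value,
      volunteer_id = .data$volunteer_id,
      rater_id = .data$rater_id
    ) |>
    dplyr::arrange(.data$group_id, .data$rater_id)

  new_replicate_view(
    kept, mode = "inter", parameter = parameter,
    stratum = list(rater_group = rater_group, age_group = age_group),
    extra = list(excluded_volunteers = excluded)
  )
}

#' @rdname replicate_views
#' @export
build_intra_view <- function(records, parameter, rater_group = NULL,
                             age_group = NULL) {
  sub <- filter_stratum(records, parameter, rater_group, age_group)

  completeness <- sub |>
    dplyr::distinct(.data$volunteer_id, .data$rater_id, .data$round) |>
    dplyr::count(.data$volunteer_id, .data$rater_id, name = "n_rounds")
  dropped <- completeness |>
    dplyr::filter(.data$n_rounds < 2) |>
    dplyr::select("volunteer_id", "rater_id")

  kept <- sub |>
    dplyr::anti_join(dropped, by = c("volunteer_id", "rater_id")) |>
    dplyr::transmute(
      group_id = paste(.data$volunteer_id, .data$rater_id, sep = "/"),
      value = .data$value,
      volunteer_id = .data$volunteer_id,
      rater_id = .data$rater_id,
      round = .data$round
    ) |>
    dplyr::arrange(.data$group_id, .data$round)

  new_replicate_view(
    kept, mode = "intra", parameter = parameter,
    stratum = list(rater_group = rater_group, age_group = age_group),
    extra = list(dropped_pairs = dropped)
  )
}

# k_i and within-group sum of squares per replicate group
group_stats <- function(view) {
  dplyr::summarise(
    dplyr::group_by(view, .data$group_id),
    k = dplyr::n(),
    mean = mean(.data$value),
    ss = sum((.data$value - mean(.data$value))^2),
    .groups = "drop"
  )
}
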