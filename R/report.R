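#' Configure a stratified reliability analysis
#'
#' Collects the choices that shape a [run_reliability_report()] run: which
#' parameters and rater groups to analyse, which parameters get an
#' age-group split (by default weight, length/height and MUAC — waist and
#' calf circumference are usually measured in one age band only, so a split
#' is uninformative there), which published threshold sets to classify
#' against, and the Bland-Altman conventions.
#'
#' @param parameters Parameters to analyse (subset of [tem_parameters()]).
#' @param rater_groups Rater groups to analyse.
#' @param age_split Parameters that additionally get per-age-group rows.
#' @param thresholds A threshold tibble (see [built_in_thresholds()]).
#' @param loa_multiplier Limits-of-agreement width in SDs (default 2).
#' @param intra_sign Intra-rater difference convention, see
#'   [bland_altman_intra()].
#' @param age_breaks Age-group boundaries, see [assign_age_group()].
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(parameters = tem_parameters(),
                            rater_groups = tem_rater_groups(),
                            age_split = c("weight", "length_height", "muac"),
                            thresholds = built_in_thresholds(
                              c("carsley2019", "icc_excellent")),
                            loa_multiplier = 2,
                            intra_sign = c("r2_minus_r1", "r1_minus_r2"),
                            age_breaks = c(2, 12)) {
  check_parameter(parameters)
  check_rater_group(rater_groups)
  check_parameter(age_split)
  stopifnot(loa_multiplier > 0)
  structure(
    list(parameters = parameters, rater_groups = rater_groups,
         age_split = age_split, thresholds = thresholds,
         loa_multiplier = loa_multiplier,
         intra_sign = match.arg(intra_sign), age_breaks = age_breaks),
    class = "analysis_config"
  )
}

#' Run the full stratified reliability report
#'
#' For every configured (parameter, rater group) and, for age-split
#' parameters, every age stratum, builds the inter-rater and intra-rater
#' replicate views and computes the observation count `n`, TEM, %TEM, the
#' coefficient of reliability R and the one-way random-effects ICC. Whole
#' rater groups are then compared parameter by parameter and mode by mode
#' with the TEM F statistic, and every row is classified against the
#' configured threshold sets. Strata with insufficient data (no volunteers,
#' or no volunteer seen by two raters) yield rows of `NA` markers — never an
#' error — so a partial exercise still produces a complete report skeleton.
#'
#' @param records A measurement tibble (see [read_measurements()]).
#' @param config An [analysis_config()].
#' @return A `reliability_report`: a tibble with one row per
#'   (parameter, rater group, age stratum, mode) carrying `n`, `n_groups`,
#'   `grand_mean`, `between_sd`, `tem`, `pct_tem`, `r_coef`, `icc`. The TEM
#'   comparisons and threshold classifications are attached and retrievable
#'   with [report_comparisons()] and [report_classification()].
#' @examples
#' rec <- study_like_dataset(seed = 1)
#' rep <- run_reliability_report(rec)
#' report_comparisons(rep)
#' @export
run_reliability_report <- function(records, config = analysis_config()) {
  stopifnot(is.data.frame(records), inherits(config, "analysis_config"))
  records <- add_age_group(records, breaks = config$age_breaks)

  strata <- purrr::map_dfr(config$parameters, function(p) {
    ages <- if (p %in% config$age_split) c(NA_character_, tem_age_groups())
            else NA_character_
    tidyr::expand_grid(parameter = p, rater_group = config$rater_groups,
                       age_group = ages, mode = c("inter", "intra"))
  })

  rows <- purrr::pmap_dfr(strata, function(parameter, rater_group,
                                           age_group, mode) {
    ag <- if (is.na(age_group)) NULL else age_group
    view <- if (mode == "inter") {
      build_inter_view(records, parameter, rater_group, ag)
    } else {
      build_intra_view(records, parameter, rater_group, ag)
    }
    smry <- tem_summary(view)
    icc <- if (nrow(view) > 0 && dplyr::n_distinct(view$group_id) >= 2) {
      icc_oneway(view)
    } else {
      NA_real_
    }
    dplyr::bind_cols(
      tibble::tibble(parameter = parameter, rater_group = rater_group,
                     age_group = ifelse(is.na(age_group), "all", age_group),
                     mode = mode),
      smry, tibble::tibble(icc = icc)
    )
  })

  n_undef <- sum(is.na(rows$tem))
  if (n_undef > 0) {
    warn(paste0(n_undef, " report row(s) have undefined statistics ",
                "(insufficient data in the stratum)."))
  }

  comparisons <- build_comparisons(rows, config)
  classification <- classify_reliability(rows, config$thresholds)

  structure(
    rows,
    comparisons = comparisons,
    classification = classification,
    config = config,
    class = c("reliability_report", class(rows))
  )
}

# TEM F comparison between the first two configured rater groups, per
# parameter and mode, on the whole-sample rows
build_comparisons <- function(rows, config) {
  if (length(config$rater_groups) < 2) {
    return(tibble::tibble())
  }
  ga <- config$rater_groups[1]
  gb <- config$rater_groups[2]
  whole <- dplyr::filter(rows, .data$age_group == "all")
  purrr::map_dfr(config$parameters, function(p) {
    purrr::map_dfr(c("inter", "intra"), function(m) {
      a <- dplyr::filter(whole, .data$parameter == p, .data$mode == m,
                         .data$rater_group == ga)
      b <- dplyr::filter(whole, .data$parameter == p, .data$mode == m,
                         .data$rater_group == gb)
      if (nrow(a) == 0 || nrow(b) == 0 ||
          is.na(a$tem) || is.na(b$tem) || a$tem == 0 || b$tem == 0) {
        cmp <- tibble::tibble(f_stat = NA_real_, df1 = NA_real_,
                              df2 = NA_real_, p_value = NA_real_,
                              tem_a = NA_real_, tem_b = NA_real_,
                              direction = NA_character_)
      } else {
        cmp <- compare_tem(a$tem, a$n, b$tem, b$n)
      }
      dplyr::bind_cols(
        tibble::tibble(parameter = p, mode = m, group_a = ga, group_b = gb),
        cmp
      )
    })
  })
}

#' @rdname run_reliability_report
#' @param report A `reliability_report`.
#' @export
report_comparisons <- function(report) {
  attr(report, "comparisons")
}

#' @rdname run_reliability_report
#' @export
report_classification <- function(report) {
  attr(report, "classification")
}

#' @export
print.reliability_report <- function(x, digits = 3, ...) {
  cat("Reliability report:", nrow(x), "strata\n")
  shown <- dplyr::mutate(
    tibble::as_tibble(x),
    dplyr::across(dplyr::where(is.double), ~ round(.x, digits))
  )
  print(shown, n = Inf)
  cmp <- report_comparisons(x)
  if (!is.null(cmp) && nrow(cmp) > 0) {
    cat("\nTEM comparisons (", cmp$group_a[1], " vs ", cmp$group_b[1],
        "):\n", sep = "")
    print(dplyr::mutate(cmp, dplyr::across(dplyr::where(is.double),
                                           ~ round(.x, digits))), n = Inf)
  }
  invisible(x)
}

#' @method tidy reliability_report
#' @export
tidy.reliability_report <- function(x, ...) {
  out <- tibble::as_tibble(x)
  attr(out, "comparisons") <- NULL
  attr(out, "classification") <- NULL
  attr(out, "config") <- NULL
  out
}

#' @method glance reliability_report
#' @export
glance.reliability_report <- function(x, ...) {
  cls <- report_classification(x)
  tibble::tibble(
    n_strata = nrow(x),
    n_parameters = dplyr::n_distinct(x$parameter),
    n_undefined = sum(is.na(x$tem)),
    n_observations = sum(x$n, na.rm = TRUE),
    prop_rules_passed = if (nrow(cls) > 0) mean(cls$pass, na.rm = TRUE)
                        else NA_real_
  )
}

#' @method autoplot reliability_report
#' @export
autoplot.reliability_report <- function(object, statistic = "pct_tem", ...) {
  stopifnot(statistic %in% c("tem", "pct_tem", "r_coef", "icc"))
  dat <- tibble::as_tibble(object)
  dat$stratum <- paste(dat$parameter, dat$age_group, sep = "\n")
  ggplot2::ggplot(
    dat, ggplot2::aes(x = .data$stratum, y = .data[[statistic]],
                      colour = .data$mode, shape = .data$rater_group)
  ) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5),
                        size = 2, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = statistic) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Write a reliability report to disk
#'
#' Writes the report in machine and human form: `reliability_report.csv`,
#' `tem_comparisons.csv` and `classification.csv` at full numeric precision
#' (so a read-back is numerically identical), plus `reliability_report.md`,
#' a markdown table rounded to 3 decimals with undefined statistics shown as
#' `NA`. Output is deterministic: the same report writes byte-identical
#' files.
#'
#' @param report A `reliability_report`.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "reliability_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    report = file.path(dir, "reliability_report.csv"),
    comparisons = file.path(dir, "tem_comparisons.csv"),
    classification = file.path(dir, "classification.csv"),
    markdown = file.path(dir, "reliability_report.md")
  )
  readr::write_csv(tidy(report), paths[["report"]])
  readr::write_csv(report_comparisons(report), paths[["comparisons"]])
  cls <- report_classification(report)
  readr::write_csv(cls, paths[["classification"]])
  writeLines(render_report_md(report), paths[["markdown"]])
  invisible(paths)
}

render_report_md <- function(report, digits = 3) {
  fmt <- function(x) {
    ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
  }
  dat <- tibble::as_tibble(report)
  header <- c(
    "# Reliability report",
    "",
    "| parameter | rater group | age group | mode | n | TEM | %TEM | R | ICC |",
    "|---|---|---|---|---|---|---|---|---|"
  )
  body <- sprintf(
    "| %s | %s | %s | %s | %s | %s | %s | %s | %s |",
    dat$parameter, dat$rater_group, dat$age_group, dat$mode,
    ifelse(is.na(dat$n), "NA", dat$n),
    fmt(dat$tem), fmt(dat$pct_tem), fmt(dat$r_coef), fmt(dat$icc)
  )
  cmp <- report_comparisons(report)
  cmp_lines <- character()
  if (!is.null(cmp) && nrow(cmp) > 0) {
    cmp_lines <- c(
      "",
      sprintf("## TEM comparison: %s vs %s", cmp$group_a[1], cmp$group_b[1]),
      "",
      "| parameter | mode | F | p |",
      "|---|---|---|---|",
      sprintf("| %s | %s | %s | %s |", cmp$parameter, cmp$mode,
              fmt(cmp$f_stat), fmt(cmp$p_value))
    )
  }
  c(header, body, cmp_lines)
}
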