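#' Reliability acceptability thresholds
#'
#' Published cutoffs against which reliability statistics are judged. Four
#' rule sets are built in:
#'
#' * `"carsley2019"`: %TEM below 2.0 for weight and length/height
#'   (paediatric primary-care repeatability benchmark).
#' * `"perini_beginner"`: %TEM below 2.0 (inter-rater) / 1.5 (intra-rater)
#'   for weight and height — the beginner anthropometrist standard.
#' * `"perini_experienced"`: %TEM below 1.5 (inter-rater) / 1.0
#'   (intra-rater) — the experienced anthropometrist standard.
#' * `"icc_excellent"`: ICC and R above 0.90, the conventional "excellent
#'   reliability" bar.
#'
#' A threshold set is a tibble with columns `set`, `rule`, `statistic`
#' (`pct_tem`, `icc` or `r_coef`), `mode` (`inter`, `intra` or `any`),
#' `parameters` (list-column of parameter names, `NULL` = all), `op`
#' (`"<"` or `">"`) and `cutoff`. Custom sets can be built with
#' [threshold_set()] or loaded from YAML/JSON with [read_thresholds()].
#'
#' @param names Character vector of built-in set names (any subset of the
#'   four above).
#' @return A threshold tibble (rows of all requested sets).
#' @examples
#' built_in_thresholds(c("carsley2019", "icc_excellent"))
#' @export
built_in_thresholds <- function(names = c("carsley2019", "perini_beginner",
                                          "perini_experienced",
                                          "icc_excellent")) {
  all <- dplyr::bind_rows(
    threshold_set("carsley2019", rule = "pct_tem_lt_2",
                  statistic = "pct_tem", mode = "any", op = "<", cutoff = 2,
                  parameters = c("weight", "length_height")),
    threshold_set("perini_beginner", rule = "inter_pct_tem_lt_2",
                  statistic = "pct_tem", mode = "inter", op = "<", cutoff = 2,
                  parameters = c("weight", "length_height")),
    threshold_set("perini_beginner", rule = "intra_pct_tem_lt_1.5",
                  statistic = "pct_tem", mode = "intra", op = "<",
                  cutoff = 1.5, parameters = c("weight", "length_height")),
    threshold_set("perini_experienced", rule = "inter_pct_tem_lt_1.5",
                  statistic = "pct_tem", mode = "inter", op = "<",
                  cutoff = 1.5, parameters = c("weight", "length_height")),
    threshold_set("perini_experienced", rule = "intra_pct_tem_lt_1",
                  statistic = "pct_tem", mode = "intra", op = "<", cutoff = 1,
                  parameters = c("weight", "length_height")),
    threshold_set("icc_excellent", rule = "icc_gt_0.9",
                  statistic = "icc", mode = "any", op = ">", cutoff = 0.9),
    threshold_set("icc_excellent", rule = "r_gt_0.9",
                  statistic = "r_coef", mode = "any", op = ">", cutoff = 0.9)
  )
  unknown <- setdiff(names, unique(all$set))
  if (length(unknown) > 0) {
    abort(paste0("Unknown threshold set(s): ", paste(unknown, collapse = ", ")))
  }
  dplyr::filter(all, .data$set %in% names)
}

#' @rdname built_in_thresholds
#' @param set,rule Identifiers of the rule (rule names must be unique within
#'   a set).
#' @param statistic One of `"pct_tem"`, `"icc"`, `"r_coef"`.
#' @param mode `"inter"`, `"intra"` or `"any"`.
#' @param op `"<"` or `">"`; the rule passes when `statistic op cutoff`.
#' @param cutoff Positive cutoff value.
#' @param parameters Parameter names the rule applies to; `NULL` for all.
#' @export
threshold_set <- function(set, rule, statistic, mode, op, cutoff,
                          parameters = NULL) {
  stopifnot(statistic %in% c("pct_tem", "icc", "r_coef"),
            mode %in% c("inter", "intra", "any"),
            op %in% c("<", ">"), cutoff > 0)
  if (!is.null(parameters)) check_parameter(parameters)
  tibble::tibble(
    set = set, rule = rule, statistic = statistic, mode = mode,
    parameters = list(parameters), op = op, cutoff = cutoff
  )
}

#' Load threshold rules from a YAML or JSON file
#'
#' The file holds a list of rule objects with fields `set`, `rule`,
#' `statistic`, `mode`, `op`, `cutoff` and optional `parameters` (list of
#' parameter names).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A threshold tibble as described in [built_in_thresholds()].
#' @export
read_thresholds <- function(path) {
  ext <- tolower(tools::file_ext(path))
  rules <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    rlang::check_installed("jsonlite")
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    abort("Threshold files must be .yaml, .yml or .json.")
  }
  purrr::map_dfr(rules, function(r) {
    threshold_set(
      set = r$set, rule = r$rule, statistic = r$statistic, mode = r$mode,
      op = r$op, cutoff = r$cutoff,
      parameters = if (!is.null(r$parameters)) unlist(r$parameters)
    )
  })
}

#' Classify reliability results against threshold rules
#'
#' Evaluates each applicable rule of a threshold set against each row of a
#' reliability result table (e.g. a [run_reliability_report()] output or a
#' [tem_summary()] row with `mode` and `parameter` columns). A rule applies
#' when its `mode` matches (or is `any`) and the row's parameter is in its
#' scope. Rules referencing a statistic that is `NA` (or absent) in a row
#' are reported with `pass = NA` (not evaluable), never silently skipped.
#'
#' @param results A data frame with columns `parameter`, `mode` and the
#'   statistic columns referenced by the rules.
#' @param thresholds A threshold tibble (default: all built-in sets).
#' @return A long tibble: one row per (result row x applicable rule) with
#'   `parameter`, `mode`, any stratum columns present, `set`, `rule`,
#'   `statistic`, `value`, `op`, `cutoff`, `pass` (logical, `NA` = not
#'   evaluable).
#' @examples
#' res <- tibble::tibble(parameter = "weight", mode = "inter",
#'                       pct_tem = 0.923, icc = 0.999, r_coef = 0.999)
#' classify_reliability(res, built_in_thresholds("carsley2019"))
#' @export
classify_reliability <- function(results, thresholds = built_in_thresholds()) {
  stopifnot(is.data.frame(results),
            all(c("parameter", "mode") %in% names(results)))
  id_cols <- intersect(c("parameter", "rater_group", "age_group", "mode"),
                       names(results))
  out <- purrr::map_dfr(seq_len(nrow(results)), function(i) {
    row <- results[i, ]
    param <- as.character(row$parameter)
    purrr::map_dfr(seq_len(nrow(thresholds)), function(j) {
      th <- thresholds[j, ]
      scope <- th$parameters[[1]]
      applies <- (th$mode == "any" || th$mode == as.character(row$mode)) &&
        (is.null(scope) || param %in% scope)
      if (!applies) return(NULL)
      value <- if (th$statistic %in% names(row)) row[[th$statistic]] else NA_real_
      pass <- if (is.na(value)) NA else if (th$op == "<") {
        value < th$cutoff
      } else {
        value > th$cutoff
      }
      dplyr::bind_cols(
        row[id_cols],
        tibble::tibble(set = th$set, rule = th$rule,
                       statistic = th$statistic, value = value,
                       op = th$op, cutoff = th$cutoff, pass = pass)
      )
    })
  })
  out
}
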