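#' Read a long-format measurement table from CSV
#'
#' Reads one row per (volunteer, rater, parameter, round) observation from an
#' RFC-4180 CSV file. Required columns (matched case-insensitively, after
#' applying `col_map`): `volunteer_id`, `rater_id`, `rater_group`,
#' `parameter`, `round`, `value`, `age_years`; `site_id` is optional. Rows
#' whose `value`, `round` or `age_years` cannot be parsed, whose `round` is
#' outside \{1, 2\}, whose `value` is not positive, or whose `parameter` /
#' `rater_group` is not in the package vocabulary are not silently dropped:
#' they are removed from the returned table and collected in the `problems`
#' attribute with their file row numbers.
#'
#' Duplicate (volunteer, rater, parameter, round) keys are an error by
#' default because silently averaging or keeping them would bias the
#' technical error of measurement downward; `duplicates = "keep_first"`
#' retains the first occurrence with a warning.
#'
#' @param path Path to a CSV file with a header row.
#' @param col_map Optional named character vector mapping standard column
#'   names to the names used in the file, e.g.
#'   `c(volunteer_id = "subject", value = "measurement")`.
#' @param duplicates `"error"` (default) or `"keep_first"`.
#'
#' @return A tibble of validated measurement records with typed columns
#'   (`parameter` and `rater_group` as factors, `round` integer, `value` and
#'   `age_years` double, `site_id` character). Rejected rows are in
#'   `attr(, "problems")`, a tibble with columns `row`, `column`, `reason`.
#' @seealso [validate_measurements()], [write_measurements()]
#' @export
read_measurements <- function(path, col_map = NULL,
                              duplicates = c("error", "keep_first")) {
  duplicates <- match.arg(duplicates)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) abort(paste0("Empty measurement file: ", path))
  as_measurements(raw, col_map = col_map, duplicates = duplicates)
}

#' Coerce a raw data frame into a validated measurement table
#'
#' The in-memory counterpart of [read_measurements()]: applies the same
#' column resolution, type coercion, row-level screening and duplicate
#' policy to a data frame assembled by other means.
#'
#' @param data A data frame with the measurement columns (any types).
#' @inheritParams read_measurements
#' @return As [read_measurements()].
#' @export
as_measurements <- function(data, col_map = NULL,
                            duplicates = c("error", "keep_first")) {
  duplicates <- match.arg(duplicates)
  required <- c("volunteer_id", "rater_id", "rater_group", "parameter",
                "round", "value", "age_years")

  nm <- tolower(names(data))
  if (!is.null(col_map)) {
    # col_map: standard_name = file_name
    for (std in names(col_map)) {
      hit <- match(tolower(col_map[[std]]), nm)
      if (!is.na(hit)) nm[hit] <- std
    }
  }
  names(data) <- nm
  missing_cols <- setdiff(required, nm)
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"site_id" %in% nm) data$site_id <- NA_character_

  n <- nrow(data)
  chr <- function(x) trimws(as.character(x))
  num <- function(x) suppressWarnings(as.numeric(chr(x)))

  volunteer_id <- chr(data$volunteer_id)
  rater_id     <- chr(data$rater_id)
  rater_group  <- normalise_token(data$rater_group)
  parameter    <- normalise_token(data$parameter)
  round_num    <- num(data$round)
  value        <- num(data$value)
  age_years    <- num(data$age_years)
  site_id      <- chr(data$site_id)

  problems <- list()
  flag <- function(bad, column, reason) {
    if (any(bad)) {
      problems[[length(problems) + 1]] <<- tibble::tibble(
        row = which(bad), column = column, reason = reason
      )
    }
    bad
  }

  bad <- flag(is.na(value), "value", "value is missing or not numeric")
  bad <- bad | flag(!is.na(value) & value <= 0, "value",
                    "value must be positive")
  bad <- bad | flag(is.na(round_num) | round_num != as.integer(round_num),
                    "round", "round is missing or not an integer")
  bad <- bad | flag(!is.na(round_num) & !(round_num %in% c(1, 2)), "round",
                    "round must be 1 or 2")
  bad <- bad | flag(is.na(age_years), "age_years",
                    "age_years is missing or not numeric")
  bad <- bad | flag(!is.na(age_years) & age_years < 0, "age_years",
                    "age_years must be non-negative")
  bad <- bad | flag(!parameter %in% tem_parameters(), "parameter",
                    "unknown parameter")
  bad <- bad | flag(!rater_group %in% tem_rater_groups(), "rater_group",
                    "unknown rater group")

  problems <- if (length(problems) > 0) {
    dplyr::arrange(dplyr::bind_rows(problems), .data$row)
  } else {
    tibble::tibble(row = integer(), column = character(),
                   reason = character())
  }

  keep <- !bad
  records <- tibble::tibble(
    volunteer_id = volunteer_id[keep],
    rater_id = rater_id[keep],
    rater_group = factor(rater_group[keep], levels = tem_rater_groups()),
    parameter = factor(parameter[keep], levels = tem_parameters()),
    round = as.integer(round_num[keep]),
    value = value[keep],
    age_years = age_years[keep],
    site_id = site_id[keep]
  )

  key_dup <- duplicated(records[c("volunteer_id", "rater_id", "parameter",
                                  "round")])
  if (any(key_dup)) {
    dups <- records[key_dup, c("volunteer_id", "rater_id", "parameter",
                               "round")]
    msg <- paste0(
      sum(key_dup), " duplicate (volunteer, rater, parameter, round) record(s), e.g. ",
      dups$volunteer_id[1], "/", dups$rater_id[1], "/",
      as.character(dups$parameter[1]), "/round ", dups$round[1]
    )
    if (duplicates == "error") {
      abort(paste0(msg, ". Use duplicates = \"keep_first\" to keep the first occurrence."))
    }
    warn(paste0(msg, "; keeping first occurrence."))
    records <- records[!key_dup, ]
  }

  attr(records, "problems") <- problems
  records
}

#' @rdname read_measurements
#' @param records A measurement tibble.
#' @export
write_measurements <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

# lowercase, collapse spaces/hyphens to underscore: "Site Lead" -> "site_lead"
normalise_token <- function(x) {
  gsub("[ -]+", "_", tolower(trimws(as.character(x))))
}

#' Validate a measurement table
#'
#' Screens an already-typed measurement table for the design-level issues
#' that matter to reliability analysis:
#' duplicate (volunteer, rater, parameter, round) keys, values off the
#' instrument precision grid (0.01 kg for weight, 0.1 cm otherwise, within
#' 1e-9 — a warning, not an error, because converted units can legitimately
#' sit off-grid), and volunteers measured by a single rater within a
#' (parameter, rater group) stratum, who cannot contribute to inter-rater
#' statistics and are excluded by [build_inter_view()].
#'
#' @param records A measurement tibble as returned by [read_measurements()].
#' @return A `tem_validation` object (list) with counts, a tibble per issue
#'   class, and a character vector of warnings. Print it for a summary.
#' @export
validate_measurements <- function(records) {
  stopifnot(is.data.frame(records))
  problems <- attr(records, "problems") %||%
    tibble::tibble(row = integer(), column = character(),
                   reason = character())

  dup_tbl <- records |>
    dplyr::count(.data$volunteer_id, .data$rater_id, .data$parameter,
                 .data$round, name = "n_copies") |>
    dplyr::filter(.data$n_copies > 1)

  off_grid <- records |>
    dplyr::mutate(
      precision = parameter_precision(as.character(.data$parameter)),
      .off = !on_grid(.data$value, .data$precision)
    ) |>
    dplyr::filter(.data$.off) |>
    dplyr::select("volunteer_id", "rater_id", "parameter", "round",
                  "value", "precision")

  single_rater <- records |>
    dplyr::filter(.data$round == 1L) |>
    dplyr::distinct(.data$parameter, .data$rater_group, .data$volunteer_id,
                    .data$rater_id) |>
    dplyr::count(.data$parameter, .data$rater_group, .data$volunteer_id,
                 name = "n_raters") |>
    dplyr::filter(.data$n_raters < 2)

  warnings <- character()
  if (nrow(problems) > 0) {
    warnings <- c(warnings, paste0(nrow(problems),
                                   " row-level parse problem(s) recorded at read time"))
  }
  if (nrow(dup_tbl) > 0) {
    warnings <- c(warnings, paste0(nrow(dup_tbl),
                                   " duplicated (volunteer, rater, parameter, round) key(s)"))
  }
  if (nrow(off_grid) > 0) {
    warnings <- c(warnings, paste0(nrow(off_grid),
                                   " value(s) off the instrument precision grid"))
  }
  if (nrow(single_rater) > 0) {
    warnings <- c(warnings, paste0(nrow(single_rater),
                                   " volunteer-stratum combination(s) with a single rater (excluded from inter-rater analysis)"))
  }

  structure(
    list(
      n_records = nrow(records),
      n_volunteers = dplyr::n_distinct(records$volunteer_id),
      n_raters = dplyr::n_distinct(records$rater_id),
      parse_problems = problems,
      duplicates = dup_tbl,
      off_grid = off_grid,
      single_rater = single_rater,
      warnings = warnings
    ),
    class = "tem_validation"
  )
}

#' @export
print.tem_validation <- function(x, ...) {
  cat("Measurement validation report\n")
  cat("  records:   ", x$n_records, "\n", sep = "")
  cat("  volunteers:", x$n_volunteers, "\n", sep = " ")
  cat("  raters:    ", x$n_raters, "\n", sep = "")
  if (length(x$warnings) == 0) {
    cat("  no issues found\n")
  } else {
    cat("  issues:\n")
    for (w in x$warnings) cat("   - ", w, "\n", sep = "")
  }
  invisible(x)
}

#' @method tidy tem_validation
#' @export
tidy.tem_validation <- function(x, ...) {
  tibble::tibble(
    issue = c("parse_problems", "duplicates", "off_grid", "single_rater"),
    n = c(nrow(x$parse_problems), nrow(x$duplicates), nrow(x$off_grid),
          nrow(x$single_rater))
  )
}
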