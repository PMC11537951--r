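# Shared vocabulary: measured parameters, rater groups, age strata.

#' Measurement vocabulary
#'
#' The five anthropometric parameters handled by the package, the two rater
#' groups of a standardisation exercise, and the three volunteer age strata.
#' These are the factor levels used throughout: `weight` is recorded in kg,
#' all other parameters (length/height and the three circumferences) in cm.
#'
#' @format Character vectors.
#' @name vocabulary
NULL

#' @rdname vocabulary
#' @export
tem_parameters <- function() {
  c("weight", "length_height", "muac", "waist", "calf")
}

#' @rdname vocabulary
#' @export
tem_rater_groups <- function() {
  c("site_lead", "fieldworker")
}

#' @rdname vocabulary
#' @export
tem_age_groups <- function() {
  c("under2", "two_to_12", "over12")
}

#' Units and instrument precision per parameter
#'
#' Weight is measured in kg on a 0.01 kg scale grid; all other parameters are
#' measured in cm to the nearest 0.1 cm. Values off this grid are flagged by
#' [validate_measurements()] as warnings, since legitimate data (for example
#' after unit conversion) can violate it.
#'
#' @param parameter Character vector of parameter names
#'   (see [tem_parameters()]).
#'
#' @return Character vector of units, or numeric vector of grid spacings, one
#'   per element of `parameter`.
#' @examples
#' parameter_units(c("weight", "muac"))
#' parameter_precision("weight")
#' @export
parameter_units <- function(parameter) {
  check_parameter(parameter)
  ifelse(parameter == "weight", "kg", "cm")
}

#' @rdname parameter_units
#' @export
parameter_precision <- function(parameter) {
  check_parameter(parameter)
  ifelse(parameter == "weight", 0.01, 0.1)
}

check_parameter <- function(parameter) {
  bad <- setdiff(unique(as.character(parameter)), tem_parameters())
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown parameter(s): ", paste(bad, collapse = ", "),
      ". Known parameters: ", paste(tem_parameters(), collapse = ", "), "."
    ))
  }
  invisible(parameter)
}

check_rater_group <- function(rater_group) {
  bad <- setdiff(unique(as.character(rater_group)), tem_rater_groups())
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown rater group(s): ", paste(bad, collapse = ", "),
      ". Known groups: ", paste(tem_rater_groups(), collapse = ", "), "."
    ))
  }
  invisible(rater_group)
}

# TRUE where x sits on a grid of spacing h (within tol, absolute)
on_grid <- function(x, h, tol = 1e-9) {
  abs(x / h - round(x / h)) * h <= tol
}
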