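#' Configure the synthetic standardisation-exercise generator
#'
#' The generator draws measurements from the additive variance-components
#' model the reliability analysis assumes:
#' \deqn{x_{v,r,round} = \mathrm{grid}(\mu_v + b_r + \varepsilon),}
#' with volunteer trait \eqn{\mu_v \sim N(\mu_{pop}, \sigma_b^2)}, rater
#' systematic bias \eqn{b_r \sim N(0, \sigma_r^2)} (constant across a
#' rater's measurements of a parameter), replicate error
#' \eqn{\varepsilon \sim N(0, \sigma_e^2)}, all independent, and
#' \eqn{\mathrm{grid}} the instrument rounding (0.01 kg for weight, 0.1 cm
#' otherwise; disable with `rounding = FALSE`). Under this model the
#' population intra-rater TEM is \eqn{\sigma_e}, the inter-rater TEM is
#' \eqn{\sqrt{\sigma_e^2 + \sigma_r^2}}, and the single-rater reliability is
#' \eqn{\rho = \sigma_b^2 / (\sigma_b^2 + \sigma_r^2 + \sigma_e^2)}.
#'
#' A (parameter, age group) cell is generated only if `traits` has a row for
#' it, which is how the default configuration restricts waist and calf
#' circumference to the over-12 stratum. Infant length is harder to measure
#' than other parameters; `infant_length_factor` multiplies
#' \eqn{\sigma_e} for `length_height` in the `under2` stratum (default 2).
#'
#' @param traits Tibble with columns `parameter`, `age_group`, `mu`,
#'   `sigma_b`: population mean and between-subject SD per cell. Default
#'   [default_synth_traits()].
#' @param errors Tibble with columns `rater_group`, `parameter`, `sigma_e`,
#'   `sigma_r`. Default [default_synth_errors()] (pure repeatability error,
#'   `sigma_r = 0`; setting `sigma_r > 0` creates the inter > intra TEM
#'   ordering seen in field data).
#' @param design Named list (by rater group) of [synth_design()] specs.
#' @param rounding Apply instrument rounding? Default `TRUE`.
#' @param infant_length_factor Multiplier on `sigma_e` for under-2
#'   length/height. Default 2.
#'
#' @return A `synth_config` list.
#' @seealso [generate_dataset()], [study_like_dataset()]
#' @export
synth_config <- function(traits = default_synth_traits(),
                         errors = default_synth_errors(),
                         design = default_synth_design(),
                         rounding = TRUE,
                         infant_length_factor = 2) {
  stopifnot(
    all(c("parameter", "age_group", "mu", "sigma_b") %in% names(traits)),
    all(c("rater_group", "parameter", "sigma_e", "sigma_r") %in% names(errors)),
    all(traits$mu > 0), all(traits$sigma_b >= 0),
    all(errors$sigma_e >= 0), all(errors$sigma_r >= 0),
    length(design) >= 1, !is.null(names(design)),
    infant_length_factor > 0
  )
  check_parameter(traits$parameter)
  check_rater_group(names(design))
  structure(
    list(traits = tibble::as_tibble(traits),
         errors = tibble::as_tibble(errors),
         design = design, rounding = rounding,
         infant_length_factor = infant_length_factor),
    class = "synth_config"
  )
}

#' @rdname synth_config
#' @param n_volunteers Named integer vector: volunteers per age group, e.g.
#'   `c(under2 = 27, two_to_12 = 26, over12 = 22)`.
#' @param n_raters Size of the rater pool for this rater group.
#' @param k_prob Named numeric vector of probabilities over
#'   raters-per-volunteer counts (names are the counts, all at least 2).
#'   Default [default_k_prob()]. A fixed design uses e.g. `c("4" = 1)`.
#' @param rounds Measurement rounds per rater (fixed at 2 in a standard
#'   exercise).
#' @export
synth_design <- function(n_volunteers, n_raters, k_prob = default_k_prob(),
                         rounds = 2L) {
  stopifnot(!is.null(names(n_volunteers)),
            all(names(n_volunteers) %in% tem_age_groups()),
            all(n_volunteers >= 1), n_raters >= 2,
            !is.null(names(k_prob)), all(as.integer(names(k_prob)) >= 2),
            all(k_prob >= 0), sum(k_prob) > 0, rounds >= 1)
  list(n_volunteers = n_volunteers, n_raters = n_raters,
       k_prob = k_prob / sum(k_prob), rounds = as.integer(rounds))
}

#' @rdname synth_config
#' @export
default_synth_traits <- function() {
  tibble::tribble(
    ~parameter,      ~age_group,  ~mu, ~sigma_b,
    "weight",        "under2",      9,      1.5,
    "weight",        "two_to_12",  25,      8,
    "weight",        "over12",     70,     15,
    "length_height", "under2",     72,      8,
    "length_height", "two_to_12", 120,     20,
    "length_height", "over12",    165,      9,
    "muac",          "under2",     15,      1.5,
    "muac",          "two_to_12",  18,      2.5,
    "muac",          "over12",     28,      4,
    "waist",         "over12",     85,     12,
    "calf",          "over12",     36,      4
  )
}

#' @rdname synth_config
#' @export
default_synth_errors <- function() {
  fw <- tibble::tribble(
    ~parameter,      ~sigma_e,
    "weight",        0.2,
    "length_height", 0.8,
    "muac",          0.5,
    "waist",         1.5,
    "calf",          0.8
  )
  dplyr::bind_rows(
    dplyr::mutate(fw, rater_group = "fieldworker", sigma_r = 0),
    dplyr::mutate(fw, rater_group = "site_lead", sigma_e = .data$sigma_e / 2,
                  sigma_r = 0)
  ) |>
    dplyr::select("rater_group", "parameter", "sigma_e", "sigma_r")
}

#' @rdname synth_config
#' @export
default_synth_design <- function() {
  list(
    site_lead = synth_design(
      n_volunteers = c(under2 = 5, two_to_12 = 5, over12 = 5),
      n_raters = 12
    ),
    fieldworker = synth_design(
      n_volunteers = c(under2 = 27, two_to_12 = 26, over12 = 22),
      n_raters = 46
    )
  )
}

#' @rdname synth_config
#' @export
default_k_prob <- function() {
  # 2-11 raters per volunteer, median 4 (cumulative mass reaches 0.5 at 4)
  p <- c(0.15, 0.20, 0.25, 0.15, 0.08, 0.06, 0.04, 0.03, 0.02, 0.02)
  names(p) <- as.character(2:11)
  p
}

age_range <- function(age_group) {
  switch(age_group,
         under2 = c(0.2, 1.9),
         two_to_12 = c(2, 12),
         over12 = c(13, 65),
         abort(paste0("Unknown age group: ", age_group)))
}

#' Generate a synthetic standardisation-exercise dataset
#'
#' Draws a full long-format measurement table from the variance-components
#' model described in [synth_config()], together with the ground truth
#' implied by the configuration (the population TEMs and reliabilities each
#' stratum should recover).
#'
#' @param config A [synth_config()] object.
#' @param seed Optional integer seed; the run is fully reproducible given
#'   the seed and does not disturb the caller's RNG state.
#' @return A list with `records` (measurement tibble in the
#'   [read_measurements()] schema) and `truth` (tibble per parameter x age
#'   group x rater group: `mu`, `sigma_b`, `sigma_e`, `sigma_r`,
#'   `tem_intra`, `tem_inter`, `pct_tem_intra`, `rho_inter`, `rho_intra`).
#' @examples
#' sim <- generate_dataset(synth_config(), seed = 42)
#' dplyr::count(sim$records, parameter)
#' @export
generate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (!is.null(seed)) withr::local_seed(seed)

  records <- purrr::imap_dfr(config$design, function(spec, g) {
    generate_group(config, spec, g)
  })
  list(records = records, truth = synth_truth(config))
}

generate_group <- function(config, spec, rater_group) {
  rater_ids <- sprintf("%s_r%02d", substr(rater_group, 1, 2),
                       seq_len(spec$n_raters))

  err <- dplyr::filter(config$errors, .data$rater_group == !!rater_group)
  # per-rater systematic bias, one draw per (rater, parameter)
  bias <- tidyr::crossing(rater_id = rater_ids,
                          parameter = unique(config$traits$parameter)) |>
    dplyr::left_join(err, by = "parameter") |>
    dplyr::mutate(b = stats::rnorm(dplyr::n(), 0, .data$sigma_r)) |>
    dplyr::select("rater_id", "parameter", "b")

  # volunteers with ages and assigned rater subsets
  vols <- purrr::imap_dfr(spec$n_volunteers, function(nv, ag) {
    rng <- age_range(ag)
    tibble::tibble(
      age_group = ag,
      volunteer_id = sprintf("%s_%s_v%02d", substr(rater_group, 1, 2),
                             ag, seq_len(nv)),
      age_years = stats::runif(nv, rng[1], rng[2])
    )
  })
  k_values <- as.integer(names(spec$k_prob))
  ks <- k_values[sample.int(length(k_values), nrow(vols), replace = TRUE,
                            prob = spec$k_prob)]
  ks <- pmin(ks, spec$n_raters)
  assignment <- purrr::map2_dfr(vols$volunteer_id, ks, function(v, k) {
    tibble::tibble(volunteer_id = v, rater_id = sample(rater_ids, k))
  })

  # latent volunteer traits, one draw per (volunteer, parameter) cell
  vol_param <- vols |>
    dplyr::inner_join(config$traits, by = "age_group",
                      relationship = "many-to-many") |>
    dplyr::mutate(mu_v = stats::rnorm(dplyr::n(), .data$mu, .data$sigma_b))

  obs <- vol_param |>
    dplyr::inner_join(assignment, by = "volunteer_id",
                      relationship = "many-to-many") |>
    tidyr::crossing(round = seq_len(spec$rounds)) |>
    dplyr::left_join(bias, by = c("rater_id", "parameter")) |>
    dplyr::left_join(err, by = "parameter") |>
    dplyr::mutate(
      sigma_e_eff = .data$sigma_e *
        ifelse(.data$parameter == "length_height" &
                 .data$age_group == "under2",
               config$infant_length_factor, 1),
      latent = .data$mu_v + .data$b +
        stats::rnorm(dplyr::n(), 0, .data$sigma_e_eff),
      precision = parameter_precision(.data$parameter),
      value = if (config$rounding) {
        pmax(round(.data$latent / .data$precision) * .data$precision,
             .data$precision)
      } else {
        .data$latent
      }
    )

  tibble::tibble(
    volunteer_id = obs$volunteer_id,
    rater_id = obs$rater_id,
    rater_group = factor(rater_group, levels = tem_rater_groups()),
    parameter = factor(obs$parameter, levels = tem_parameters()),
    round = as.integer(obs$round),
    value = obs$value,
    age_years = obs$age_years,
    site_id = NA_character_
  ) |>
    dplyr::arrange(.data$volunteer_id, .data$parameter, .data$rater_id,
                   .data$round)
}

synth_truth <- function(config) {
  tidyr::crossing(config$traits,
                  rater_group = names(config$design)) |>
    dplyr::inner_join(config$errors, by = c("rater_group", "parameter")) |>
    dplyr::mutate(
      sigma_e = .data$sigma_e *
        ifelse(.data$parameter == "length_height" &
                 .data$age_group == "under2",
               config$infant_length_factor, 1),
      tem_intra = .data$sigma_e,
      tem_inter = sqrt(.data$sigma_e^2 + .data$sigma_r^2),
      pct_tem_intra = 100 * .data$tem_intra / .data$mu,
      rho_inter = .data$sigma_b^2 /
        (.data$sigma_b^2 + .data$sigma_r^2 + .data$sigma_e^2),
      rho_intra = (.data$sigma_b^2 + .data$sigma_r^2) /
        (.data$sigma_b^2 + .data$sigma_r^2 + .data$sigma_e^2)
    ) |>
    dplyr::select("parameter", "age_group", "rater_group", "mu", "sigma_b",
                  "sigma_e", "sigma_r", "tem_intra", "tem_inter",
                  "pct_tem_intra", "rho_inter", "rho_intra")
}

#' Study-like synthetic dataset preset
#'
#' Convenience preset reproducing the design shape of a national-survey
#' standardisation exercise: 15 volunteers (5 per age stratum) measured by a
#' pool of 12 site-lead teams, and 75 volunteers (27 / 26 / 22 per stratum)
#' measured by a pool of 46 fieldworker teams; each volunteer measured by
#' 2-11 teams (median 4), two rounds each, five parameters with waist and
#' calf circumference restricted to the over-12 stratum, and instrument
#' rounding applied. The anthropometric means and SDs are plausible package
#' defaults (e.g. infant weight about 9 kg, adult height about 165 cm), not
#' values taken from any particular survey.
#'
#' @param seed Integer seed for reproducibility.
#' @return A measurement tibble; the generating ground truth is attached as
#'   `attr(, "truth")`.
#' @examples
#' rec <- study_like_dataset(seed = 1)
#' dplyr::n_distinct(rec$volunteer_id)
#' @export
study_like_dataset <- function(seed = 1L) {
  sim <- generate_dataset(synth_config(), seed = seed)
  out <- sim$records
  attr(out, "truth") <- sim$truth
  out
}
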