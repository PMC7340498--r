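#' Generate synthetic small-area sampling units
#'
#' Places `n_units` survey sampling units uniformly on the configured
#' bounding box and draws their covariates: rural/urban status, altitude
#' (log-normal, most units below 400 m), long-term mean temperature (lapses
#' with altitude), female illiteracy (higher in rural units) and resident
#' population size.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per unit: `unit_id`, `lon`, `lat`, `rural`,
#'   `altitude_m`, `temperature_c`, `female_illiteracy`, `population`.
#' @seealso [generate_population()] for the age-sex split.
#' @export
#' @examples
#' units <- generate_units(sim_config(n_units = 10, seed = 1))
generate_units <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created by sim_config().",
          class = "snakeburden_config_error")
  }
  set.seed(config$seed)
  n <- config$n_units
  bb <- config$bbox
  tibble(
    unit_id = sprintf("U%05d", seq_len(n)),
    lon = runif(n, bb[["lon_min"]], bb[["lon_max"]]),
    lat = runif(n, bb[["lat_min"]], bb[["lat_max"]]),
    rural = runif(n) < config$rural_share,
    altitude_m = rlnorm(n, meanlog = log(150), sdlog = 1),
    female_illiteracy = NA_real_,
    population = pmax(50, round(rlnorm(
      n, meanlog = log(config$mean_unit_population) - 0.125, sdlog = 0.5)))
  ) |>
    mutate(
      temperature_c = 26 - 5 * .data$altitude_m / 1000 + rnorm(n, sd = 1),
      female_illiteracy = ifelse(.data$rural, rbeta(n, 5, 4), rbeta(n, 2, 5)),
      .after = "altitude_m"
    )
}

# Approximate 2001-census-like age distribution of India (proportions by
# 5-year band), normalized to sum to 1. Synthetic/approximate values.
india_age_proportions <- function() {
  p <- c(10.7, 12.5, 12.1, 9.7, 8.9, 8.1, 7.4, 6.9, 5.7, 4.8, 3.6, 2.7,
         2.5, 1.8, 1.4, 0.7, 0.4, 0.2)
  setNames(p / sum(p), age_band_labels())
}

#' Standard population for age-standardization
#'
#' An 18-band standard population approximating the Indian census-2001 age
#' distribution (synthetic approximation, proportions summing to 1), used as
#' the default standard in [age_standardize()].
#'
#' @return A tibble with columns `age_band` and `weight`.
#' @export
india_standard_population <- function() {
  p <- india_age_proportions()
  tibble(age_band = names(p), weight = unname(p))
}

#' Split unit populations into age-sex cells
#'
#' Expands the per-unit resident population into the 18 five-year age bands
#' and two sexes, using a fixed India-like age distribution and a 51.5% male
#' share. Fractional person counts are kept (they act as person-year
#' denominators downstream).
#'
#' @param units Output of [generate_units()].
#' @param config The same [sim_config()].
#' @return A tibble `unit_id`, `sex`, `age_band`, `population`.
#' @export
generate_population <- function(units, config) {
  stopifnot_cols(units, c("unit_id", "population"), "units")
  props <- india_age_proportions()
  tidyr::expand_grid(
    unit_id = units$unit_id,
    sex = c("male", "female"),
    age_band = names(props)
  ) |>
    left_join(units[, c("unit_id", "population")], by = "unit_id") |>
    mutate(
      population = .data$population *
        ifelse(.data$sex == "male", 0.515, 0.485) *
        props[.data$age_band],
      age_band = factor(.data$age_band, levels = age_band_labels())
    )
}
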