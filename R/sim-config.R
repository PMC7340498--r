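#' Simulation configuration for the synthetic surveillance world
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults emulate the structure of the Indian Million Death Study world:
#' a national snakebite death rate of 4.8 per 100,000 person-years, 92%
#' immediate dual-coder agreement, a monsoon-peaked seasonal curve with
#' peak-to-trough ratio exp(2 * 0.663) = 3.77 peaking in mid-July (day 196),
#' 23% of snakebite deaths occurring in hospital, a rural population share of
#' 0.75 with a rural excess risk chosen so that about 94% of snakebite deaths
#' are rural, and an all-cause crude death rate of 7.5 per 1,000.
#'
#' @param n_units Number of small-area sampling units (>= 2).
#' @param seed Integer seed; identical config + seed gives identical output.
#' @param years Calendar years covered by the simulated surveillance.
#' @param base_rate National snakebite death rate per 100,000 person-years.
#' @param spatial_range Correlation length (degrees) of the latent spatial
#'   log relative-risk field.
#' @param spatial_sd Marginal standard deviation of the latent log-RR field.
#'   Zero turns the field off.
#' @param seasonal_amplitude Amplitude of the annual log-scale sinusoid of
#'   daily death intensity (>= 0); the peak/trough ratio is
#'   `exp(2 * seasonal_amplitude)`. Zero gives uniform dates.
#' @param seasonal_peak_day Day of year (1-365) at which the seasonal curve
#'   peaks.
#' @param coder_agreement Probability that the second physician also codes a
#'   true snakebite death as X20.
#' @param hospital_fraction Probability that a snakebite death occurs in
#'   hospital.
#' @param rural_share Probability that a unit is rural (and hence the expected
#'   rural share of the simulated population).
#' @param covariate_effects Named list of log-RR effects applied to centred
#'   unit covariates: `rural` (per unit indicator), `altitude` (per metre),
#'   `female_illiteracy` (per unit fraction, rural units only),
#'   `temperature` (per degree C).
#' @param annual_trend Log-linear annual trend of the snakebite rate
#'   (e.g. -0.008 for a 0.8%/year decline); centred at 2010.
#' @param other_death_rate All-cause (non-snakebite) crude death rate per
#'   person-year used to interleave non-snakebite records.
#' @param mean_unit_population Mean resident population per sampling unit.
#' @param sampling_weights Named numeric of SRS-style sampling weights,
#'   elements `rural` and `urban`; the weight scheme is a user input.
#' @param grid_dim Integer vector `c(nx, ny)`: resolution of the latent field
#'   grid (also the default prediction grid).
#' @param bbox Named numeric bounding box (`lon_min`, `lon_max`, `lat_min`,
#'   `lat_max`) on which units are placed.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_units = 50, seed = 1)
#' cfg$base_rate
sim_config <- function(n_units,
                       seed = 1L,
                       years = 2001:2014,
                       base_rate = 4.8,
                       spatial_range = 4,
                       spatial_sd = 0.3,
                       seasonal_amplitude = 0.663,
                       seasonal_peak_day = 196L,
                       coder_agreement = 0.92,
                       hospital_fraction = 0.23,
                       rural_share = 0.75,
                       covariate_effects = list(rural = 1.65,
                                                altitude = -0.0014,
                                                female_illiteracy = 0.5,
                                                temperature = 0),
                       annual_trend = 0,
                       other_death_rate = 0.0075,
                       mean_unit_population = 1000,
                       sampling_weights = c(rural = 1, urban = 1),
                       grid_dim = c(20L, 20L),
                       bbox = c(lon_min = 68, lon_max = 90,
                                lat_min = 8, lat_max = 34)) {
  chk_num <- function(x, field, lo = -Inf, hi = Inf, strict_lo = FALSE) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
        x < lo || x > hi || (strict_lo && x <= lo)) {
      abort(sprintf("Invalid configuration field `%s`.", field),
            class = "snakeburden_config_error")
    }
  }
  if (!is.numeric(n_units) || length(n_units) != 1 || n_units < 2) {
    abort("Invalid configuration field `n_units` (need >= 2).",
          class = "snakeburden_config_error")
  }
  chk_num(base_rate, "base_rate", lo = 0, strict_lo = TRUE)
  chk_num(spatial_range, "spatial_range", lo = 0, strict_lo = TRUE)
  chk_num(spatial_sd, "spatial_sd", lo = 0)
  chk_num(seasonal_amplitude, "seasonal_amplitude", lo = 0)
  chk_num(seasonal_peak_day, "seasonal_peak_day", lo = 1, hi = 365)
  chk_num(coder_agreement, "coder_agreement", lo = 0, hi = 1)
  chk_num(hospital_fraction, "hospital_fraction", lo = 0, hi = 1)
  chk_num(rural_share, "rural_share", lo = 0, hi = 1)
  chk_num(other_death_rate, "other_death_rate", lo = 0)
  chk_num(mean_unit_population, "mean_unit_population", lo = 0,
          strict_lo = TRUE)
  chk_num(annual_trend, "annual_trend")
  if (!all(c("rural", "urban") %in% names(sampling_weights)) ||
      any(sampling_weights <= 0)) {
    abort("Invalid configuration field `sampling_weights`.",
          class = "snakeburden_config_error")
  }
  eff <- utils::modifyList(
    list(rural = 0, altitude = 0, female_illiteracy = 0, temperature = 0),
    as.list(covariate_effects))
  structure(
    list(n_units = as.integer(n_units), seed = as.integer(seed),
         years = as.integer(years), base_rate = base_rate,
         spatial_range = spatial_range, spatial_sd = spatial_sd,
         seasonal_amplitude = seasonal_amplitude,
         seasonal_peak_day = as.integer(seasonal_peak_day),
         coder_agreement = coder_agreement,
         hospital_fraction = hospital_fraction,
         rural_share = rural_share, covariate_effects = eff,
         annual_trend = annual_trend,
         other_death_rate = other_death_rate,
         mean_unit_population = mean_unit_population,
         sampling_weights = sampling_weights,
         grid_dim = as.integer(grid_dim), bbox = bbox),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_units, "units,", length(x$years), "years,",
      "base rate", x$base_rate, "/100k, seed", x$seed, "\n")
  invisible(x)
}

# Relative age pattern of snakebite death rates: broad-band shape
# (0-14: 4.5, 15-29: 3.1, 30-69: 5.8, 70+: 5.0) expanded to 5-year bands and
# normalized so the age-standardized rate equals the configured base rate.
snakebite_age_multipliers <- function() {
  bands <- age_band_labels()
  lo <- c(seq(0, 85, 5))
  mult <- ifelse(lo < 15, 4.5, ifelse(lo < 30, 3.1, ifelse(lo < 70, 5.8, 5.0)))
  mult <- mult / sum(india_age_proportions() * mult)
  setNames(mult, bands)
}

# All-cause age pattern (deaths per person-year, unnormalized); rescaled in
# the generator so the population-weighted crude rate matches the config.
allcause_age_pattern <- function() {
  setNames(
    c(1700, 150, 100, 150, 200, 220, 250, 300, 400, 550, 800, 1200,
      2000, 3200, 5200, 8500, 14000, 25000) / 1e5,
    age_band_labels())
}
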