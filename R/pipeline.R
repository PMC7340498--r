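# End-to-end pipeline on a synthetic world: simulate -> classify -> rates ->
# seasonality -> spatial risk -> prevalence -> coverage.

#' Run the full burden-estimation pipeline on a synthetic world
#'
#' Generates a synthetic surveillance world from `config` and pushes it
#' through every stage: dual-coder classification and plausible-range
#' bounds; weighted cause fractions with moving-average smoothing,
#' zero-stratum interpolation and envelope scaling; age-specific and
#' standardized rates, risk before 70 and spline trend projections;
#' seasonal model, monsoon share and altitude profile; national and
#' geostatistical Poisson models with a predicted relative- and
#' absolute-risk surface and population at risk; literature case-fatality
#' regression with scenario-based bite totals; and a surveillance coverage
#' table.
#'
#' @param config A [sim_config()].
#' @param std Standard population for age-standardization.
#' @param grid_dim Prediction-grid resolution `c(nx, ny)`.
#' @param geo_knots Spatial knot resolution for the geostatistical model.
#' @param n_studies,true_cfr Literature-study simulation settings.
#' @return A named list with every intermediate and final product (see
#'   [write_burden_outputs()] for the file manifest).
#' @export
run_burden_pipeline <- function(config, std = india_standard_population(),
                                grid_dim = c(20L, 20L), geo_knots = c(7L, 7L),
                                n_studies = 78, true_cfr = 0.032) {
  units <- generate_units(config)
  population <- generate_population(units, config)
  surface <- generate_true_surface(units, config)
  deaths <- generate_deaths(units, population, surface, config)

  classified <- classify_records(deaths, review = review_from_truth(deaths))
  bounds <- coding_bounds(classified)

  fractions <- weighted_fractions(classified, by = "year") |>
    moving_average() |>
    interpolate_zero_strata()
  envelope <- make_envelope(deaths)
  totals <- scale_to_envelope(fractions, envelope)

  # age-specific rates per year from included snakebite deaths
  pop_band <- population |>
    mutate(age_band = as.character(.data$age_band)) |>
    group_by(.data$age_band) |>
    summarise(population = sum(.data$population), .groups = "drop")
  band_rates <- classified |>
    filter(.data$is_snakebite) |>
    mutate(year = lubridate::year(.data$date_of_death),
           age_band = as.character(cut_age_band(.data$age))) |>
    count(.data$year, .data$age_band, name = "deaths") |>
    tidyr::complete(year = config$years, age_band = age_band_labels(),
                    fill = list(deaths = 0L)) |>
    left_join(pop_band, by = "age_band") |>
    mutate(rate = .data$deaths / .data$population * 1e5)
  std_rates <- age_standardize(
    band_rates[, c("year", "age_band", "rate")], std = std, by = "year")
  risk70_by_year <- band_rates |>
    filter(.data$age_band %in% bands_0_69()) |>
    group_by(.data$year) |>
    summarise(risk_before_70_pct = risk_before_70(pick("age_band", "rate")),
              .groups = "drop")
  trend <- spline_trend(
    tibble(year = std_rates$year, value = std_rates$standardized_rate),
    predict_years = 2000:2019)

  snake <- filter(classified, .data$is_snakebite)
  hosp_frac <- mean(snake$place == "hospital")
  split <- hospital_split(sum(totals$estimated_deaths, na.rm = TRUE),
                          hosp_frac)

  seasonal <- fit_seasonal(snake$date_of_death)
  monsoon <- monsoon_share(snake$date_of_death)
  altitude <- altitude_profile(snake, units, n_years = length(config$years))

  nat_in <- national_rate_input(classified, population, config$years)
  nat_fit <- fit_national_rates(nat_in)
  geo_data <- unit_death_counts(classified, units) |>
    left_join(unit_expected_deaths(population, nat_fit, config$years),
              by = "unit_id") |>
    mutate(female_illiteracy_rural = .data$female_illiteracy * .data$rural)
  covs <- c("rural", "female_illiteracy_rural", "altitude_m", "temperature_c")
  geo_fit <- fit_geostatistical_rr(geo_data, covariates = covs,
                                   knots = geo_knots)
  units_cov <- mutate(units, female_illiteracy_rural =
                        .data$female_illiteracy * .data$rural)
  grid <- make_prediction_grid(units_cov, covariates = covs,
                               nx = grid_dim[1], ny = grid_dim[2])
  rr_surface <- predict_rr_grid(geo_fit, grid)
  national_risk <- mean(risk70_by_year$risk_before_70_pct)
  abs_surface <- absolute_risk(rr_surface, national_risk)
  par_tbl <- population_at_risk(abs_surface,
                                grid[, c("lon", "lat", "population")])

  studies <- generate_literature_studies(n_studies, true_cfr,
                                         dispersion = 0.002,
                                         seed = config$seed + 5L)
  cfr_fit <- estimate_cfr(studies)
  scenarios <- total_bites(default_prevalence_scenarios())
  envenom <- partition_envenomation(attr(scenarios, "range")[["max"]])

  # emulated official reporting: regions are the rural/urban strata and the
  # government captures a tenth of in-hospital deaths
  est_region <- snake |>
    mutate(region = ifelse(.data$rural, "rural", "urban")) |>
    group_by(.data$region) |>
    summarise(est_total_deaths = n(),
              in_hospital_fraction = mean(.data$place == "hospital"),
              .groups = "drop")
  rep_region <- est_region |>
    transmute(region = .data$region,
              reported_bites = .data$est_total_deaths * 2,
              reported_deaths = 0.1 * .data$est_total_deaths *
                .data$in_hospital_fraction)
  coverage <- coverage_table(rep_region, est_region,
                             aggregate_name = "national")

  list(config = config, units = units, population = population,
       surface = surface, deaths = deaths, classified = classified,
       bounds = bounds, fractions = fractions, envelope = envelope,
       totals = totals, band_rates = band_rates, std_rates = std_rates,
       risk70_by_year = risk70_by_year, trend = trend,
       hospital_split = split, seasonal = seasonal, monsoon = monsoon,
       altitude = altitude, national_fit = nat_fit, geo_data = geo_data,
       geo_fit = geo_fit, grid = grid, rr_surface = rr_surface,
       abs_surface = abs_surface, population_at_risk = par_tbl,
       studies = studies, cfr_fit = cfr_fit, scenarios = scenarios,
       envenomations = envenom, coverage = coverage)
}

#' Write the pipeline's declared output files
#'
#' Emits the pipeline products as plain-text files under `dir`: units.csv,
#' deaths.csv, studies.csv, truth.json, coded_counts.json, fractions.csv,
#' rates.csv, totals.csv, seasonal_curve.csv, altitude_profile.csv,
#' rr_surface.csv, absolute_risk.csv, population_at_risk.json, cfr.json,
#' prevalence.csv, burden_summary.json and coverage.csv.
#'
#' @param results Output of [run_burden_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_burden_outputs <- function(results, dir) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    abort("Writing outputs requires the jsonlite package.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  wcsv <- function(x, f) write.csv(x, p(f), row.names = FALSE)
  wjson <- function(x, f) jsonlite::write_json(x, p(f), auto_unbox = TRUE,
                                               digits = NA)
  wcsv(results$units, "units.csv")
  wcsv(results$deaths, "deaths.csv")
  wcsv(results$studies, "studies.csv")
  wjson(list(base_rate = results$config$base_rate,
             seasonal_amplitude = results$config$seasonal_amplitude,
             coder_agreement = results$config$coder_agreement,
             spatial_sd = results$config$spatial_sd,
             spatial_range = results$config$spatial_range),
        "truth.json")
  wjson(as.list(results$bounds), "coded_counts.json")
  wcsv(results$fractions, "fractions.csv")
  wcsv(results$band_rates, "rates.csv")
  wcsv(results$totals, "totals.csv")
  wcsv(results$seasonal$curve, "seasonal_curve.csv")
  wcsv(results$altitude, "altitude_profile.csv")
  wcsv(as_tibble(results$rr_surface), "rr_surface.csv")
  wcsv(as_tibble(results$abs_surface), "absolute_risk.csv")
  wjson(split(results$population_at_risk,
              seq_len(nrow(results$population_at_risk))),
        "population_at_risk.json")
  wjson(list(cfr = results$cfr_fit$cfr,
             ci = as.list(results$cfr_fit$ci),
             n_used = results$cfr_fit$n_used),
        "cfr.json")
  wcsv(as_tibble(results$scenarios), "prevalence.csv")
  wjson(list(
    national_deaths = sum(results$totals$estimated_deaths, na.rm = TRUE),
    standardized_rate = mean(results$std_rates$standardized_rate),
    risk_before_70_pct = mean(results$risk70_by_year$risk_before_70_pct),
    monsoon_share = results$monsoon$share,
    total_bites_range = as.list(attr(results$scenarios, "range"))),
    "burden_summary.json")
  wcsv(results$coverage, "coverage.csv")
  invisible(list.files(dir, full.names = TRUE))
}
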