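# Simulated observation process: snakebite and other deaths with dual-coder
# ICD-10 codes, dates drawn from the seasonal curve, and SRS-style weights.

# Snakebite death rate per 100,000 person-years by 5-year band.
snakebite_band_rates <- function(config) {
  config$base_rate * snakebite_age_multipliers()
}

# Centring constants for covariates in the generator's linear predictor;
# fixed so that a typical unit has covariate multiplier ~1.
covariate_centres <- function(config) {
  list(rural = config$rural_share, altitude = 250,
       female_illiteracy_rural = 0.4, temperature = 25)
}

# Per-unit covariate log-RR contribution (centred covariates).
unit_covariate_lp <- function(units, config) {
  eff <- config$covariate_effects
  cc <- covariate_centres(config)
  eff$rural * (units$rural - cc$rural) +
    eff$altitude * (units$altitude_m - cc$altitude) +
    eff$female_illiteracy *
      (units$female_illiteracy * units$rural - cc$female_illiteracy_rural) +
    eff$temperature * (units$temperature_c - cc$temperature)
}

# Expected snakebite deaths per unit x sex x age band x year (the analytic
# truth the recovery tests compare against).
expected_death_grid <- function(units, population, surface, config) {
  missing_units <- setdiff(units$unit_id, surface$units$unit_id)
  if (length(missing_units) > 0) {
    abort(sprintf("Units missing from surface: %s",
                  paste(head(missing_units, 5), collapse = ", ")),
          class = "snakeburden_alignment_error")
  }
  rates <- snakebite_band_rates(config)
  # covariate multiplier, centred to population-weighted mean 1 so the
  # configured base rate stays the national rate
  cm <- exp(unit_covariate_lp(units, config))
  cm <- cm / weighted.mean(cm, w = units$population)
  lp <- tibble(unit_id = units$unit_id, cov_lp = log(cm))
  population |>
    left_join(surface$units, by = "unit_id") |>
    left_join(lp, by = "unit_id") |>
    tidyr::expand_grid(year = config$years) |>
    mutate(expected = .data$population *
             rates[as.character(.data$age_band)] / 1e5 *
             exp(.data$log_rr + .data$cov_lp +
                   config$annual_trend * (.data$year - 2010)))
}

#' Analytic expected snakebite deaths per unit
#'
#' The generator's ground truth: expected snakebite deaths by unit (summed
#' over ages, sexes, and the configured years), from population x band rate
#' x unit relative risk x covariate terms x trend.
#'
#' @inheritParams generate_deaths
#' @return Tibble `unit_id`, `expected`.
#' @export
true_expected_deaths <- function(units, population, surface, config) {
  expected_death_grid(units, population, surface, config) |>
    group_by(.data$unit_id) |>
    summarise(expected = sum(.data$expected), .groups = "drop")
}

#' Simulate verbal-autopsy death records
#'
#' Draws snakebite deaths as Poisson counts with unit-level expectations
#' given by the true surface and covariates, assigns death dates from the
#' seasonal curve, and attaches two physicians' ICD-10 codes: coder 1 always
#' codes a true snakebite death X20; coder 2 codes X20 with probability
#' `coder_agreement`, otherwise X27 or X29. Non-snakebite deaths (fixed
#' small ICD-10 code list) are interleaved at the configured all-cause rate
#' with uniform dates. The true cause is retained in `cause_true`, which
#' downstream review tables may use as the adjudication result.
#'
#' @param units Output of [generate_units()].
#' @param population Output of [generate_population()].
#' @param surface Output of [generate_true_surface()] (aligned by `unit_id`).
#' @param config The same [sim_config()].
#' @return A tibble of death records: `record_id`, `unit_id`,
#'   `date_of_death`, `age`, `sex`, `place`, `rural`, `coder1_icd10`,
#'   `coder2_icd10`, `final_icd10`, `sampling_weight`, `cause_true`.
#' @export
generate_deaths <- function(units, population, surface, config) {
  grid <- expected_death_grid(units, population, surface, config)
  set.seed(config$seed + 2L)

  snake <- grid |>
    mutate(n = rpois(n(), .data$expected)) |>
    filter(.data$n > 0) |>
    tidyr::uncount(.data$n) |>
    select("unit_id", "sex", "age_band", "year")
  ns <- nrow(snake)

  other_codes <- c("I21", "I64", "J18", "A09", "C34", "K74", "R99",
                   "W74", "V89", "J44")
  pat <- allcause_age_pattern()
  # rescale the all-cause pattern so the crude rate matches the config
  wbar <- sum(india_age_proportions() * pat)
  pat <- pat * config$other_death_rate / wbar
  other <- population |>
    tidyr::expand_grid(year = config$years) |>
    mutate(n = rpois(n(), .data$population * pat[as.character(.data$age_band)])) |>
    filter(.data$n > 0) |>
    tidyr::uncount(.data$n) |>
    select("unit_id", "sex", "age_band", "year")
  no <- nrow(other)

  sample_days <- function(n, prob) {
    if (n == 0) return(integer(0))
    sample.int(365, n, replace = TRUE, prob = prob)
  }
  snake$day <- sample_days(ns, surface$seasonal$multiplier)
  other$day <- sample_days(no, rep(1, 365))

  draw_common <- function(df) {
    n <- nrow(df)
    lo <- band_lower(df$age_band)
    df |>
      mutate(
        age = lo + runif(n) * ifelse(lo >= 85, 10, 5),
        date_of_death = as.Date(sprintf("%d-01-01", .data$year)) + .data$day - 1L
      )
  }
  snake <- draw_common(snake) |>
    mutate(
      place = sample(c("hospital", "home", "other"), ns, replace = TRUE,
                     prob = c(config$hospital_fraction,
                              (1 - config$hospital_fraction) * 0.9,
                              (1 - config$hospital_fraction) * 0.1)),
      coder1_icd10 = "X20",
      coder2_icd10 = ifelse(runif(ns) < config$coder_agreement, "X20",
                            sample(c("X27", "X29"), ns, replace = TRUE)),
      final_icd10 = "X20",
      cause_true = "snakebite")
  other <- draw_common(other) |>
    mutate(
      place = sample(c("hospital", "home", "other"), no, replace = TRUE,
                     prob = c(0.35, 0.55, 0.10)),
      coder1_icd10 = sample(other_codes, no, replace = TRUE),
      coder2_icd10 = .data$coder1_icd10,
      final_icd10 = .data$coder1_icd10,
      cause_true = "other")

  bind_rows(snake, other) |>
    left_join(units[, c("unit_id", "rural")], by = "unit_id") |>
    mutate(sampling_weight = unname(
      config$sampling_weights[ifelse(.data$rural, "rural", "urban")])) |>
    arrange(.data$unit_id, .data$date_of_death, .data$age) |>
    mutate(record_id = sprintf("D%07d", row_number())) |>
    select("record_id", "unit_id", "date_of_death", "age", "sex", "place",
           "rural", "coder1_icd10", "coder2_icd10", "final_icd10",
           "sampling_weight", "cause_true")
}
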