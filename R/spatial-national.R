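# National Bayesian Poisson rate model: age-sex cell effects (no global
# intercept) plus a linear time trend centred at a reference year, fitted by
# penalized Newton (MAP) with a Gaussian-posterior Laplace approximation.

#' Aggregate classified records into a national rate-model input
#'
#' Builds the deaths / person-years table by 5-year age band, sex and year,
#' restricted to ages 0-69, that [fit_national_rates()] consumes. Person-year
#' denominators are national sums of the unit populations (one year of
#' exposure per calendar year).
#'
#' @param classified Output of [classify_records()]; records with
#'   `is_snakebite`, `age`, `sex`, `date_of_death`.
#' @param population Output of [generate_population()] (or any tibble
#'   `unit_id`, `sex`, `age_band`, `population`).
#' @param years Calendar years to include.
#' @return Tibble `age_band`, `sex`, `year`, `deaths`, `person_years`.
#' @export
national_rate_input <- function(classified, population, years) {
  stopifnot_cols(classified, c("is_snakebite", "age", "sex", "date_of_death"),
                 "classified")
  py <- population |>
    mutate(age_band = as.character(.data$age_band)) |>
    filter(.data$age_band %in% bands_0_69()) |>
    group_by(.data$sex, .data$age_band) |>
    summarise(person_years = sum(.data$population), .groups = "drop")
  d <- classified |>
    filter(.data$is_snakebite, .data$age < 70,
           lubridate::year(.data$date_of_death) %in% years) |>
    mutate(age_band = as.character(cut_age_band(.data$age)),
           year = lubridate::year(.data$date_of_death)) |>
    count(.data$sex, .data$age_band, .data$year, name = "deaths")
  tidyr::expand_grid(sex = c("male", "female"), age_band = bands_0_69(),
                     year = years) |>
    left_join(d, by = c("sex", "age_band", "year")) |>
    left_join(py, by = c("sex", "age_band")) |>
    mutate(deaths = tidyr::replace_na(.data$deaths, 0L),
           person_years = tidyr::replace_na(.data$person_years, 0))
}

#' Fit the national Bayesian Poisson rate model
#'
#' Poisson likelihood with log link and log person-years offset; one free
#' parameter per age-sex cell (no global intercept) plus a linear time trend
#' centred at `ref_year`, so the cell effects are the log death rates in the
#' reference year. Weakly informative independent normal priors are placed
#' on all parameters; the posterior is summarized by its Laplace (Gaussian)
#' approximation at the mode.
#'
#' @param data Tibble `age_band`, `sex`, `year`, `deaths`, `person_years`
#'   (ages 0-69 in 5-year bands). Cells with zero exposure are dropped with
#'   a warning.
#' @param ref_year Reference year for the trend (default 2010).
#' @param prior_sd_cell,prior_sd_trend Prior standard deviations for the
#'   cell log-rates and the annual trend.
#' @return Object of class `national_rate_fit` with elements `rates` (tibble
#'   `age_band`, `sex`, `rate`, `lower`, `upper` per 100,000 at `ref_year`),
#'   `trend` (one-row tibble `estimate`, `lower`, `upper` on the annual log
#'   scale), `coef`, `vcov`, `ref_year`.
#' @export
fit_national_rates <- function(data, ref_year = 2010,
                               prior_sd_cell = 10, prior_sd_trend = 1) {
  stopifnot_cols(data, c("age_band", "sex", "year", "deaths", "person_years"),
                 "data")
  zero <- data$person_years <= 0
  if (any(zero)) {
    warn(sprintf("Dropping %d cell-years with zero exposure.", sum(zero)))
    data <- data[!zero, ]
  }
  if (any(!as.character(data$age_band) %in% bands_0_69())) {
    abort("Rates model expects 5-year bands covering ages 0-69 only.",
          class = "snakeburden_validation_error")
  }
  cell <- interaction(as.character(data$age_band), data$sex, drop = TRUE,
                      sep = ":")
  X <- outer(as.character(cell), levels(cell), `==`) * 1
  colnames(X) <- levels(cell)
  X <- cbind(X, trend = data$year - ref_year)
  P <- diag(c(rep(1 / prior_sd_cell^2, nlevels(cell)), 1 / prior_sd_trend^2))
  # initialize cell effects near the crude pooled log rate
  crude <- log(pmax(sum(data$deaths), 0.5) / sum(data$person_years))
  init <- c(rep(crude, nlevels(cell)), 0)
  fit <- pois_newton(X, data$deaths, log(data$person_years), P, init = init)
  V <- chol2inv(chol(fit$H))
  se <- sqrt(diag(V))
  k <- nlevels(cell)
  parts <- strsplit(levels(cell), ":", fixed = TRUE)
  rates <- tibble(
    age_band = vapply(parts, `[`, "", 1),
    sex = vapply(parts, `[`, "", 2),
    log_rate = fit$xi[seq_len(k)], se = se[seq_len(k)]) |>
    mutate(rate = exp(.data$log_rate) * 1e5,
           lower = exp(.data$log_rate - 1.96 * .data$se) * 1e5,
           upper = exp(.data$log_rate + 1.96 * .data$se) * 1e5)
  trend <- tibble(estimate = fit$xi[k + 1],
                  lower = fit$xi[k + 1] - 1.96 * se[k + 1],
                  upper = fit$xi[k + 1] + 1.96 * se[k + 1])
  structure(
    list(rates = rates, trend = trend,
         coef = setNames(fit$xi, colnames(X)), vcov = V,
         ref_year = ref_year, data = data),
    class = "national_rate_fit")
}

#' @export
print.national_rate_fit <- function(x, ...) {
  cat("<national_rate_fit>", nrow(x$rates), "age-sex cells, trend",
      sprintf("%.3f [%.3f, %.3f] /yr\n", x$trend$estimate, x$trend$lower,
              x$trend$upper))
  invisible(x)
}

#' Expected snakebite deaths per unit under the national rates
#'
#' Multiplies each unit's age-sex person-years by the fitted national rates
#' (with the fitted time trend applied per calendar year) to obtain the
#' expected death count used as the baseline of the geostatistical
#' relative-risk model.
#'
#' @param population Tibble `unit_id`, `sex`, `age_band`, `population`.
#' @param fit A [fit_national_rates()] result.
#' @param years Calendar years of observation.
#' @return Tibble `unit_id`, `expected`.
#' @export
unit_expected_deaths <- function(population, fit, years) {
  stopifnot(inherits(fit, "national_rate_fit"))
  trend_sum <- sum(exp(fit$trend$estimate * (years - fit$ref_year)))
  population |>
    mutate(age_band = as.character(.data$age_band)) |>
    filter(.data$age_band %in% bands_0_69()) |>
    left_join(fit$rates[, c("age_band", "sex", "rate")],
              by = c("age_band", "sex")) |>
    group_by(.data$unit_id) |>
    summarise(expected = sum(.data$population * .data$rate / 1e5) * trend_sum,
              .groups = "drop")
}
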