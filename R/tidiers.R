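# broom-style tidiers for the fitted objects.

#' Tidy a national rate fit
#'
#' @param x A [fit_national_rates()] object.
#' @param ... Unused.
#' @return A tibble with one row per age-sex cell (rates per 100,000 at the
#'   reference year) plus a `trend` row on the annual log scale.
#' @export
tidy.national_rate_fit <- function(x, ...) {
  bind_rows(
    x$rates |>
      transmute(term = paste(.data$age_band, .data$sex, sep = ":"),
                type = "rate_per_100k", estimate = .data$rate,
                conf.low = .data$lower, conf.high = .data$upper),
    tibble(term = "trend", type = "log_trend_per_year",
           estimate = x$trend$estimate,
           conf.low = x$trend$lower, conf.high = x$trend$upper))
}

#' @rdname tidy.national_rate_fit
#' @export
glance.national_rate_fit <- function(x, ...) {
  tibble(n_cells = nrow(x$rates), ref_year = x$ref_year,
         trend = x$trend$estimate,
         trend_lower = x$trend$lower, trend_upper = x$trend$upper)
}

#' Tidy a geostatistical relative-risk fit
#'
#' @param x A [fit_geostatistical_rr()] object.
#' @param ... Unused.
#' @return A tibble of covariate coefficients (per SD of covariate, log-RR
#'   scale) and hyperparameters.
#' @export
tidy.geo_rr_fit <- function(x, ...) {
  bind_rows(
    if (length(x$coef) > 0)
      tibble(term = names(x$coef), type = "coefficient",
             estimate = unname(x$coef)),
    tibble(term = names(x$hyper), type = "hyperparameter",
           estimate = unname(x$hyper)))
}

#' @rdname tidy.geo_rr_fit
#' @export
glance.geo_rr_fit <- function(x, ...) {
  tibble(n_units = x$n_units, n_knots = x$n_knots,
         sd_field = x$hyper[["sd_field"]], range = x$hyper[["range"]],
         sd_unit = x$hyper[["sd_unit"]])
}

#' Tidy a case-fatality regression
#'
#' @param x An [estimate_cfr()] object.
#' @param ... Unused.
#' @return A one-row tibble for the slope (the case-fatality rate).
#' @export
tidy.cfr_fit <- function(x, ...) {
  tibble(term = "cfr", estimate = x$cfr, std.error = x$se,
         conf.low = x$ci[["lower"]], conf.high = x$ci[["upper"]])
}

#' @rdname tidy.cfr_fit
#' @export
glance.cfr_fit <- function(x, ...) {
  tibble(cfr = x$cfr, n_used = x$n_used, n_excluded = nrow(x$excluded),
         outlier_threshold = x$outlier_threshold)
}

#' Tidy a seasonal fit
#'
#' @param x A [fit_seasonal()] object.
#' @param ... Unused.
#' @return Coefficients of the harmonic Poisson regression.
#' @export
tidy.seasonal_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2])
}

#' @rdname tidy.seasonal_fit
#' @export
glance.seasonal_fit <- function(x, ...) {
  tibble(n_deaths = x$n_deaths, harmonics = x$harmonics, flat = x$flat,
         peak_day = x$peak_day, peak_value = x$peak_value,
         trough_day = x$trough_day, trough_value = x$trough_value,
         peak_trough_ratio = x$peak_trough_ratio)
}
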