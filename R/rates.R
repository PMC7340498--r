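# Cause fractions, envelope scaling, standardized rates, risk before 70,
# spline trends and hospital splits.

#' Sampling-weighted cause fractions by stratum
#'
#' Computes, for each stratum, the sampling-weighted snakebite and total
#' death counts and their ratio (the cause fraction). Unweighted counts are
#' retained for diagnostics. The `year` stratifier is derived from
#' `date_of_death` when not already present.
#'
#' @param classified Output of [classify_records()] (needs `is_snakebite`
#'   and `sampling_weight`).
#' @param by Character vector of stratifying columns (default `"year"`).
#' @return Tibble with the `by` columns plus `weighted_snakebite`,
#'   `weighted_total`, `n_snakebite`, `n_total`, `fraction` (NA where the
#'   weighted total is zero).
#' @export
weighted_fractions <- function(classified, by = "year") {
  stopifnot_cols(classified, c("is_snakebite", "sampling_weight"),
                 "classified")
  if ("year" %in% by && !"year" %in% names(classified)) {
    stopifnot_cols(classified, "date_of_death", "classified")
    classified <- mutate(classified,
                         year = lubridate::year(.data$date_of_death))
  }
  if (any(classified$sampling_weight <= 0 |
            !is.finite(classified$sampling_weight))) {
    abort("All sampling weights must be positive and finite.",
          class = "snakeburden_validation_error")
  }
  classified |>
    group_by(across(all_of(by))) |>
    summarise(
      weighted_snakebite = sum(.data$sampling_weight * .data$is_snakebite),
      weighted_total = sum(.data$sampling_weight),
      n_snakebite = sum(.data$is_snakebite),
      n_total = n(),
      .groups = "drop") |>
    mutate(fraction = ifelse(.data$weighted_total > 0,
                             .data$weighted_snakebite / .data$weighted_total,
                             NA_real_))
}

#' Backward moving average of weighted death frequencies
#'
#' Smooths the weighted numerator and denominator (not the ratio) with a
#' lag-weighted backward window over years, then recomputes the fraction.
#' Edge years with fewer than `window` available lags use the shorter window
#' renormalized, so the first year of a frame equals its own value.
#'
#' @param fractions Output of [weighted_fractions()] including a `year`
#'   column.
#' @param window Window length in years (default 3, i.e. current plus two
#'   previous years).
#' @param lag_weights Positive weights for lags 0, 1, ..., window-1
#'   (default equal).
#' @return The input with `weighted_snakebite`, `weighted_total` and
#'   `fraction` replaced by their smoothed values.
#' @export
moving_average <- function(fractions, window = 3,
                           lag_weights = rep(1, window)) {
  stopifnot_cols(fractions, c("year", "weighted_snakebite", "weighted_total"),
                 "fractions")
  if (length(lag_weights) != window || any(lag_weights <= 0)) {
    abort("`lag_weights` must be positive and of length `window`.",
          class = "snakeburden_config_error")
  }
  strata <- setdiff(names(fractions),
                    c("year", "weighted_snakebite", "weighted_total",
                      "n_snakebite", "n_total", "fraction"))
  smooth_one <- function(x, years) {
    vapply(seq_along(x), function(i) {
      lags <- 0:(window - 1)
      j <- match(years[i] - lags, years)
      ok <- !is.na(j)
      sum(lag_weights[ok] * x[j[ok]]) / sum(lag_weights[ok])
    }, numeric(1))
  }
  fractions |>
    group_by(across(all_of(strata))) |>
    arrange(.data$year, .by_group = TRUE) |>
    mutate(
      weighted_snakebite = smooth_one(.data$weighted_snakebite, .data$year),
      weighted_total = smooth_one(.data$weighted_total, .data$year)) |>
    ungroup() |>
    mutate(fraction = ifelse(.data$weighted_total > 0,
                             .data$weighted_snakebite / .data$weighted_total,
                             NA_real_))
}

#' Interpolate cause fractions for empty strata
#'
#' Strata-years with no observed deaths (weighted total zero, i.e. missing
#' fraction) receive fractions linearly interpolated along year within the
#' stratum; leading/trailing gaps carry the nearest observed year's value.
#' Optionally, zero fractions (no snakebite deaths in a sparse stratum) can
#' be treated as missing too. A stratum whose entire series is missing is
#' left missing and reported via a warning.
#'
#' @param fractions A fractions table with `year` and `fraction`.
#' @param treat_zero_as_missing Also impute years where the fraction is
#'   exactly zero? Default `FALSE`.
#' @return The input with `fraction` imputed where possible and a logical
#'   `imputed` column flagging filled cells.
#' @export
interpolate_zero_strata <- function(fractions, treat_zero_as_missing = FALSE) {
  stopifnot_cols(fractions, c("year", "fraction"), "fractions")
  strata <- setdiff(names(fractions),
                    c("year", "weighted_snakebite", "weighted_total",
                      "n_snakebite", "n_total", "fraction", "imputed"))
  out <- fractions |>
    mutate(.target = is.na(.data$fraction) |
             (treat_zero_as_missing & .data$fraction == 0)) |>
    group_by(across(all_of(strata))) |>
    arrange(.data$year, .by_group = TRUE) |>
    mutate(
      fraction = {
        f <- ifelse(.data$.target, NA_real_, .data$fraction)
        if (all(is.na(f))) f else
          zoo::na.approx(f, x = .data$year, na.rm = FALSE, rule = 2)
      },
      imputed = .data$.target & !is.na(.data$fraction)) |>
    ungroup() |>
    select(-".target")
  if (anyNA(out$fraction)) {
    warn("Some strata have no observed years and were left missing.")
  }
  out
}

#' Scale cause fractions to a demographic death envelope
#'
#' Multiplies each stratum-year's cause fraction by the corresponding
#' all-cause envelope total (UN-style death totals) to obtain estimated
#' cause-specific deaths. Joins on `year` plus any stratifiers shared with
#' the envelope; errors if the envelope does not cover every year.
#'
#' @param fractions A fractions table with `year` and `fraction`.
#' @param envelope Tibble with `year`, `total_deaths` (and optionally finer
#'   strata columns matching the fractions table).
#' @return The fractions table with `envelope_deaths` and
#'   `estimated_deaths = fraction * envelope_deaths`.
#' @export
scale_to_envelope <- function(fractions, envelope) {
  stopifnot_cols(fractions, c("year", "fraction"), "fractions")
  stopifnot_cols(envelope, c("year", "total_deaths"), "envelope")
  if (any(envelope$total_deaths <= 0)) {
    abort("Envelope totals must be positive.",
          class = "snakeburden_validation_error")
  }
  missing_years <- setdiff(unique(fractions$year), unique(envelope$year))
  if (length(missing_years) > 0) {
    abort(sprintf("Envelope is missing year(s): %s",
                  paste(missing_years, collapse = ", ")),
          class = "snakeburden_validation_error")
  }
  keys <- intersect(names(fractions), names(envelope))
  keys <- setdiff(keys, "total_deaths")
  fractions |>
    left_join(rename(envelope, envelope_deaths = "total_deaths"), by = keys) |>
    mutate(estimated_deaths = .data$fraction * .data$envelope_deaths)
}

#' Age-standardize a set of age-specific rates
#'
#' Weighted average of age-specific rates using a fixed standard population;
#' weights are normalized to one, so scaling all standard weights leaves the
#' result unchanged. Accepts extra grouping columns (e.g. `year`).
#'
#' @param rates Tibble with `age_band`, `rate` and optional grouping columns.
#' @param std Standard population tibble `age_band`, `weight` (default
#'   [india_standard_population()]).
#' @param by Grouping columns (default: all columns except `age_band` and
#'   `rate`).
#' @return Tibble of the grouping columns plus `standardized_rate`.
#' @export
age_standardize <- function(rates, std = india_standard_population(),
                            by = NULL) {
  stopifnot_cols(rates, c("age_band", "rate"), "rates")
  stopifnot_cols(std, c("age_band", "weight"), "std")
  if (any(std$weight <= 0 | !is.finite(std$weight))) {
    abort("Standard population weights must be positive and finite.",
          class = "snakeburden_validation_error")
  }
  missing_bands <- setdiff(as.character(rates$age_band),
                           as.character(std$age_band))
  if (length(missing_bands) > 0) {
    abort(sprintf("Standard population is missing band(s): %s",
                  paste(unique(missing_bands), collapse = ", ")),
          class = "snakeburden_alignment_error")
  }
  by <- by %||% setdiff(names(rates), c("age_band", "rate"))
  rates |>
    mutate(age_band = as.character(.data$age_band)) |>
    left_join(mutate(std, age_band = as.character(.data$age_band)),
              by = "age_band") |>
    group_by(across(all_of(by))) |>
    summarise(standardized_rate = weighted.mean(.data$rate, .data$weight),
              .groups = "drop")
}

#' Cumulative risk of snakebite death before age 70
#'
#' The additive approximation: with 14 five-year band rates (per 100,000
#' person-years) covering ages 0-69, the risk in percent is
#' `sum(5 * rate / 100000) * 100`. No exponential survival correction is
#' applied; at snakebite magnitudes the difference is negligible (well below
#' 0.001 percentage points).
#'
#' @param rates Either a numeric vector of 14 band rates (ages 0-4 ...
#'   65-69) or a tibble with `age_band` and `rate` containing exactly those
#'   bands.
#' @return Risk before age 70 as a percentage.
#' @export
#' @examples
#' risk_before_70(rep(5, 14)) # 0.35
risk_before_70 <- function(rates) {
  if (is.data.frame(rates)) {
    stopifnot_cols(rates, c("age_band", "rate"), "rates")
    rates <- rates |>
      mutate(age_band = as.character(.data$age_band)) |>
      filter(.data$age_band %in% bands_0_69())
    if (!setequal(rates$age_band, bands_0_69()) ||
        nrow(rates) != 14) {
      abort("Need exactly the 14 five-year bands 0-4 ... 65-69.",
            class = "snakeburden_validation_error")
    }
    rates <- rates$rate[order(match(rates$age_band, bands_0_69()))]
  }
  if (length(rates) != 14) {
    abort("Need exactly 14 five-year band rates (ages 0-69).",
          class = "snakeburden_validation_error")
  }
  sum(5 * rates / 1e5) * 100
}

#' Cubic-spline trend with linear extrapolation
#'
#' Fits a cubic regression spline (B-spline basis with interior knots at
#' year quantiles) to an annual series, and extrapolates outside the data
#' range linearly, continuing the slope of the fitted curve at the nearest
#' boundary.
#'
#' @param series Tibble with `year` and `value`.
#' @param knots Number of interior knots (default 3).
#' @param predict_years Years at which predictions are wanted (may extend
#'   beyond the data; default: the data years).
#' @return Tibble `year`, `fitted`, `source` (`"fitted"` within the data
#'   range, `"extrapolated"` outside), with the knot locations in attribute
#'   `"knots"`.
#' @export
spline_trend <- function(series, knots = 3, predict_years = NULL) {
  stopifnot_cols(series, c("year", "value"), "series")
  series <- arrange(series, .data$year)
  n <- nrow(series)
  if (n < knots + 4) {
    abort(sprintf(
      "Only %d years for %d interior knots; reduce `knots` to at most %d.",
      n, knots, max(0, n - 4)),
      class = "snakeburden_config_error")
  }
  kq <- if (knots > 0)
    quantile(series$year, probs = seq_len(knots) / (knots + 1), names = FALSE)
  else numeric(0)
  lo <- min(series$year); hi <- max(series$year)
  basis <- function(x) splines::bs(x, knots = kq, degree = 3,
                                   Boundary.knots = c(lo, hi))
  B <- cbind(1, basis(series$year))
  beta <- qr.coef(qr(B), series$value)
  beta[is.na(beta)] <- 0
  f_in <- function(x) {
    X <- cbind(1, basis(pmin(pmax(x, lo), hi)))
    drop(X %*% beta)
  }
  h <- 1e-4
  slope_lo <- (f_in(lo + h) - f_in(lo)) / h
  slope_hi <- (f_in(hi) - f_in(hi - h)) / h
  predict_years <- sort(unique(c(predict_years %||% series$year)))
  fitted <- vapply(predict_years, function(x) {
    if (x < lo) f_in(lo) + slope_lo * (x - lo)
    else if (x > hi) f_in(hi) + slope_hi * (x - hi)
    else f_in(x)
  }, numeric(1))
  out <- tibble(year = predict_years, fitted = fitted,
                source = ifelse(predict_years < lo | predict_years > hi,
                                "extrapolated", "fitted"))
  attr(out, "knots") <- kq
  out
}

#' Split death totals into in- and out-of-hospital components
#'
#' @param total Death total(s).
#' @param in_hospital_fraction Fraction of deaths occurring in hospital, in
#'   `[0, 1]`.
#' @return Tibble `total`, `in_hospital`, `out_of_hospital` (rows recycled
#'   over the inputs); the two components sum to the total exactly.
#' @export
#' @examples
#' hospital_split(100, 0.23)
hospital_split <- function(total, in_hospital_fraction) {
  if (any(in_hospital_fraction < 0 | in_hospital_fraction > 1)) {
    abort("`in_hospital_fraction` must be in [0, 1].",
          class = "snakeburden_validation_error")
  }
  tibble(total = total,
         in_hospital = total * in_hospital_fraction,
         out_of_hospital = total * (1 - in_hospital_fraction))
}

#' Build an all-cause death envelope from simulated records
#'
#' Counts all simulated deaths per year, optionally inflated to emulate an
#' external demographic envelope exceeding the survey count.
#'
#' @param records A death-record tibble with `date_of_death`.
#' @param inflation Multiplier applied to the yearly counts (default 1).
#' @return Tibble `year`, `total_deaths`.
#' @export
make_envelope <- function(records, inflation = 1) {
  stopifnot_cols(records, "date_of_death", "records")
  records |>
    count(year = lubridate::year(.data$date_of_death)) |>
    mutate(total_deaths = .data$n * inflation, .keep = "unused")
}
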