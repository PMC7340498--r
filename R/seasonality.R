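# Harmonic Poisson model of daily mortality and altitude profiles.

#' Fit a cyclic Poisson model of daily death counts
#'
#' Pools death dates across years into a composite 365-day year (Feb 29
#' folds into Feb 28), and regresses the daily counts on sine/cosine pairs
#' of the day of year with a Poisson log link. Two harmonics (annual +
#' semi-annual) are the default: a single-peaked but asymmetric annual curve
#' needs more than one. Because the GLM has an intercept and canonical link,
#' the fitted curve sums exactly to the observed death count.
#'
#' @param dates Vector of death dates (`Date`).
#' @param harmonics Number of harmonics (>= 1).
#' @param annual_total Optional total to rescale the fitted curve to (e.g.
#'   a national annual death total when the input is a sample).
#' @return An object of class `seasonal_fit`: list with the `glm`, the
#'   `curve` tibble (`day`, `expected`), `peak_day`, `peak_value`,
#'   `trough_day`, `trough_value`, `peak_trough_ratio`, `flat` (TRUE when
#'   the fitted curve is essentially constant) and `n_deaths`.
#' @export
fit_seasonal <- function(dates, harmonics = 2, annual_total = NULL) {
  if (length(dates) == 0) {
    abort("No death dates supplied.", class = "snakeburden_validation_error")
  }
  doy <- day_of_year_365(dates)
  counts <- tabulate(doy, nbins = 365)
  if (all(counts == 0)) {
    abort("All daily counts are zero; cannot fit a seasonal model.",
          class = "snakeburden_degenerate_fit")
  }
  day <- 1:365
  H <- do.call(cbind, lapply(seq_len(harmonics), function(k) {
    cbind(sin(2 * pi * k * day / 365), cos(2 * pi * k * day / 365))
  }))
  colnames(H) <- as.vector(t(outer(seq_len(harmonics), c("sin", "cos"),
                                   function(k, f) paste0(f, k))))
  df <- data.frame(count = counts, H)
  fit <- glm(count ~ ., family = poisson(), data = df)
  expected <- unname(fitted(fit))
  scale <- if (!is.null(annual_total)) annual_total / sum(expected) else 1
  curve <- tibble(day = day, expected = expected * scale)
  flat <- max(expected) / min(expected) < 1.01
  structure(
    list(model = fit, curve = curve, harmonics = harmonics,
         peak_day = if (flat) NA_integer_ else which.max(expected),
         peak_value = max(curve$expected),
         trough_day = if (flat) NA_integer_ else which.min(expected),
         trough_value = min(curve$expected),
         peak_trough_ratio = max(expected) / min(expected),
         flat = flat, n_deaths = sum(counts), scale = scale),
    class = "seasonal_fit")
}

#' @export
print.seasonal_fit <- function(x, ...) {
  cat("<seasonal_fit>", x$harmonics, "harmonic(s),", x$n_deaths, "deaths\n")
  if (x$flat) cat("  essentially flat seasonality\n")
  else cat(sprintf("  peak day %d (%.1f), trough day %d (%.1f), ratio %.2f\n",
                   x$peak_day, x$peak_value, x$trough_day, x$trough_value,
                   x$peak_trough_ratio))
  invisible(x)
}

#' Share of deaths in the southwest monsoon (June-September)
#'
#' @param dates Vector of death dates.
#' @param by_year Also return the per-year breakdown?
#' @return One-row tibble `n`, `n_monsoon`, `share`; with `by_year = TRUE`,
#'   one row per calendar year.
#' @export
monsoon_share <- function(dates, by_year = FALSE) {
  df <- tibble(year = lubridate::year(dates),
               monsoon = lubridate::month(dates) %in% 6:9)
  if (by_year) df <- group_by(df, .data$year)
  summarise(df, n = n(), n_monsoon = sum(.data$monsoon),
            share = .data$n_monsoon / .data$n, .groups = "drop")
}

#' Crude death rates by altitude bin
#'
#' Aggregates deaths and person-years into altitude bins (default 100 m) at
#' sampling-unit level and computes the crude rate per 100,000 person-years
#' and the cumulative share of deaths below each bin's upper edge.
#'
#' @param deaths Death records with `unit_id` (already restricted to the
#'   cause of interest).
#' @param units Unit table with `unit_id`, `altitude_m`, `population`.
#' @param n_years Number of years of observation the deaths span (converts
#'   populations to person-years).
#' @param bin_width Bin width in metres (default 100).
#' @return Tibble `bin_low_m`, `bin_high_m`, `deaths`, `person_years`,
#'   `rate_per_100k`, `cum_death_share`.
#' @export
altitude_profile <- function(deaths, units, n_years, bin_width = 100) {
  stopifnot_cols(units, c("unit_id", "altitude_m", "population"), "units")
  stopifnot_cols(deaths, "unit_id", "deaths")
  if (any(units$altitude_m < 0)) {
    abort("Altitudes must be non-negative.",
          class = "snakeburden_validation_error")
  }
  units <- mutate(units,
                  bin_low_m = floor(.data$altitude_m / bin_width) * bin_width)
  d <- deaths |>
    left_join(units[, c("unit_id", "bin_low_m")], by = "unit_id") |>
    count(.data$bin_low_m, name = "deaths")
  units |>
    group_by(.data$bin_low_m) |>
    summarise(person_years = sum(.data$population) * n_years,
              .groups = "drop") |>
    left_join(d, by = "bin_low_m") |>
    mutate(deaths = tidyr::replace_na(.data$deaths, 0L)) |>
    arrange(.data$bin_low_m) |>
    mutate(bin_high_m = .data$bin_low_m + bin_width,
           rate_per_100k = .data$deaths / .data$person_years * 1e5,
           cum_death_share = cumsum(.data$deaths) / sum(.data$deaths),
           .after = "bin_low_m")
}
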