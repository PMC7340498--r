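# ggplot2 methods for the main result types.

#' Plot a fitted seasonal curve
#'
#' Expected deaths per day of the composite year, with the monsoon window
#' (June-September) shaded.
#'
#' @param object A [fit_seasonal()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.seasonal_fit <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$day,
                                             y = .data$expected)) +
    ggplot2::annotate("rect", xmin = 152, xmax = 273, ymin = -Inf,
                      ymax = Inf, alpha = 0.12) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Day of year", y = "Expected deaths per day",
                  title = "Seasonality of snakebite mortality") +
    ggplot2::theme_minimal()
}

#' Plot a risk surface
#'
#' @param object A `risk_surface` tibble from [predict_rr_grid()] or
#'   [absolute_risk()].
#' @param what Column to map to fill (default `abs_risk_pct` when present,
#'   else `rr`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.risk_surface <- function(object,
                                  what = if ("abs_risk_pct" %in%
                                             names(object)) "abs_risk_pct"
                                         else "rr", ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$lon, y = .data$lat,
                               fill = .data[[what]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = what) +
    ggplot2::theme_minimal()
}

#' Plot a case-fatality regression
#'
#' Study deaths against bites with the fitted through-origin slope; removed
#' outliers are marked.
#'
#' @param object An [estimate_cfr()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cfr_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$bites,
                                            y = .data$deaths)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_point(data = object$excluded, colour = "red", shape = 4,
                        size = 2.5) +
    ggplot2::geom_abline(intercept = 0, slope = object$cfr) +
    ggplot2::labs(x = "Bites per study", y = "Deaths per study",
                  title = sprintf("Case-fatality regression (slope %.3f)",
                                  object$cfr)) +
    ggplot2::theme_minimal()
}

#' Plot an altitude profile of crude death rates
#'
#' @param profile An [altitude_profile()] result.
#' @return A ggplot of crude rate by altitude bin.
#' @export
plot_altitude_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$bin_low_m,
                               y = .data$rate_per_100k)) +
    ggplot2::geom_col(width = diff(profile$bin_low_m[1:2]) * 0.9) +
    ggplot2::labs(x = "Altitude (m)",
                  y = "Crude death rate per 100,000 person-years") +
    ggplot2::theme_minimal()
}
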