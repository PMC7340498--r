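#' Generate the true latent risk surface and seasonal curve
#'
#' Draws a Gaussian random field with Matern (smoothness 1) covariance on a
#' coarse regular grid, interpolates it bilinearly to the unit locations,
#' and centres it so the population-weighted mean relative risk across units
#' is exactly 1. Also realizes the annual seasonal curve: 365 daily
#' multipliers proportional to
#' `exp(amplitude * cos(2 * pi * (day - peak_day) / 365))`, normalized to
#' mean 1.
#'
#' @param units Output of [generate_units()].
#' @param config The same [sim_config()]; `spatial_sd = 0` gives a flat
#'   (log-RR 0) field and `seasonal_amplitude = 0` a flat seasonal curve.
#' @return An object of class `true_surface`: a list with tibbles `grid`
#'   (`lon`, `lat`, `log_rr`), `units` (`unit_id`, `log_rr`) and `seasonal`
#'   (`day`, `multiplier`).
#' @export
generate_true_surface <- function(units, config) {
  stopifnot_cols(units, c("unit_id", "lon", "lat", "population"), "units")
  set.seed(config$seed + 1L)
  nx <- config$grid_dim[1]; ny <- config$grid_dim[2]
  bb <- config$bbox
  gx <- seq(bb[["lon_min"]], bb[["lon_max"]], length.out = nx)
  gy <- seq(bb[["lat_min"]], bb[["lat_max"]], length.out = ny)
  grid <- grid_centres(bb, nx, ny)

  if (config$spatial_sd > 0) {
    D <- as.matrix(dist(cbind(grid$lon, grid$lat)))
    S <- matern_cov(D, sd = config$spatial_sd, range = config$spatial_range) +
      diag(1e-8, nrow(grid))
    z <- drop(t(chol(S)) %*% rnorm(nrow(grid)))
  } else {
    z <- rep(0, nrow(grid))
  }
  A <- bilinear_basis(units$lon, units$lat, gx, gy)
  unit_lrr <- drop(A %*% z)
  centre <- log(weighted.mean(exp(unit_lrr), w = units$population))
  z <- z - centre
  unit_lrr <- unit_lrr - centre

  day <- 1:365
  m <- exp(config$seasonal_amplitude *
             cos(2 * pi * (day - config$seasonal_peak_day) / 365))
  m <- m / mean(m)

  structure(
    list(grid = tibble(lon = grid$lon, lat = grid$lat, log_rr = z),
         units = tibble(unit_id = units$unit_id, log_rr = unit_lrr),
         seasonal = tibble(day = day, multiplier = m),
         grid_axes = list(gx = gx, gy = gy)),
    class = "true_surface")
}

#' @export
print.true_surface <- function(x, ...) {
  cat("<true_surface>", nrow(x$grid), "grid cells,", nrow(x$units),
      "units, log-RR sd", signif(sd(x$units$log_rr), 3), "\n")
  invisible(x)
}

#' Plant a circular high-risk cluster into a true surface
#'
#' Adds `log(rr)` to the latent log relative risk of every unit and grid cell
#' within `radius` degrees of `centre`. Used to construct detection oracles
#' for the geostatistical model.
#'
#' @param surface A [generate_true_surface()] result.
#' @param units The unit tibble the surface was built from.
#' @param centre Numeric `c(lon, lat)` of the cluster centre.
#' @param radius Radius in degrees.
#' @param rr Relative risk multiplier inside the cluster (> 0).
#' @return The modified `true_surface`, with a logical attribute column
#'   `in_cluster` added to `surface$units`.
#' @export
plant_risk_cluster <- function(surface, units, centre, radius, rr) {
  stopifnot(inherits(surface, "true_surface"), rr > 0, radius > 0)
  du <- sqrt((units$lon - centre[1])^2 + (units$lat - centre[2])^2)
  dg <- sqrt((surface$grid$lon - centre[1])^2 +
               (surface$grid$lat - centre[2])^2)
  surface$units$log_rr <- surface$units$log_rr + log(rr) * (du <= radius)
  surface$units$in_cluster <- du <= radius
  surface$grid$log_rr <- surface$grid$log_rr + log(rr) * (dg <= radius)
  surface
}
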