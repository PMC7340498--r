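# Geostatistical Bayesian Poisson relative-risk model.
#
# observed_i ~ Poisson(expected_i * RR_i)
# log RR_i = x_i' beta + w(s_i) + u_i
# w: Matern (smoothness 1) Gaussian field, reduced-rank on a regular knot
#    grid with bilinear interpolation to locations
# u: iid unit-level effect (nugget)
#
# Inference is empirical-Bayes Laplace: an inner damped Newton finds the MAP
# of (beta, z, u) given the hyperparameters (field SD, range, unit SD); the
# outer optimisation maximizes the Laplace-approximate marginal posterior of
# the hyperparameters; latent posteriors are Gaussian at the joint mode.

#' Fit the geostatistical relative-risk model
#'
#' @param data Tibble with `unit_id`, `lon`, `lat`, `deaths`, `expected`
#'   (baseline expected deaths from the national rates) and the covariate
#'   columns named in `covariates`. Units with `expected <= 0` are dropped
#'   with a warning; non-finite covariates are an error.
#' @param covariates Character vector of covariate column names entering the
#'   log relative risk linearly (internally centred and scaled). May be
#'   empty.
#' @param knots Integer `c(nx, ny)` resolution of the spatial knot grid.
#' @param hyper Optional fixed hyperparameters: named list/vector with
#'   `sd_field`, `range`, `sd_unit`. When `NULL` (default) they are
#'   estimated by maximizing the Laplace marginal posterior.
#' @param prior_sd_coef Prior SD of the covariate coefficients.
#' @param margin Margin (degrees) by which the knot grid extends beyond the
#'   data extent.
#' @return Object of class `geo_rr_fit`; the per-unit posterior relative
#'   risks are in `$units` (`unit_id`, `rr`, `rr_lower`, `rr_upper`),
#'   hyperparameters in `$hyper`, coefficients via [tidy()].
#' @export
fit_geostatistical_rr <- function(data, covariates = character(),
                                  knots = c(8L, 8L), hyper = NULL,
                                  prior_sd_coef = 10, margin = 0.5) {
  stopifnot_cols(data, c("unit_id", "lon", "lat", "deaths", "expected"),
                 "data")
  stopifnot_cols(data, covariates, "data")
  drop <- data$expected <= 0
  if (any(drop)) {
    warn(sprintf("Dropping %d unit(s) with non-positive expected deaths.",
                 sum(drop)))
    data <- data[!drop, ]
  }
  p <- length(covariates)
  Xraw <- as.matrix(data[, covariates, drop = FALSE])
  if (p > 0 && any(!is.finite(Xraw))) {
    bad <- data$unit_id[!complete.cases(Xraw) | rowSums(!is.finite(Xraw)) > 0]
    abort(sprintf("Non-finite covariate value(s) for unit(s): %s",
                  paste(head(bad, 5), collapse = ", ")),
          class = "snakeburden_validation_error")
  }
  ctr <- if (p > 0) colMeans(Xraw) else numeric(0)
  scl <- if (p > 0) apply(Xraw, 2, sd) else numeric(0)
  scl[!is.finite(scl) | scl == 0] <- 1
  X <- if (p > 0) sweep(sweep(Xraw, 2, ctr), 2, scl, "/") else
    matrix(0, nrow(data), 0)

  gx <- seq(min(data$lon) - margin, max(data$lon) + margin,
            length.out = knots[1])
  gy <- seq(min(data$lat) - margin, max(data$lat) + margin,
            length.out = knots[2])
  kgrid <- tidyr::expand_grid(lat = gy, lon = gx)[, c("lon", "lat")]
  K <- nrow(kgrid)
  Dk <- as.matrix(dist(cbind(kgrid$lon, kgrid$lat)))
  A <- bilinear_basis(data$lon, data$lat, gx, gy)
  n <- nrow(data)
  C <- cbind(X, A, diag(n))
  y <- data$deaths
  offset <- log(data$expected)
  diag_extent <- sqrt(diff(range(data$lon))^2 + diff(range(data$lat))^2)

  prec_matrix <- function(sd_field, range, sd_unit) {
    Sz <- matern_cov(Dk, sd = sd_field, range = range) + diag(1e-6, K)
    Qz <- chol2inv(chol(Sz))
    P <- matrix(0, p + K + n, p + K + n)
    if (p > 0) diag(P)[seq_len(p)] <- 1 / prior_sd_coef^2
    P[p + seq_len(K), p + seq_len(K)] <- Qz
    diag(P)[p + K + seq_len(n)] <- 1 / sd_unit^2
    P
  }

  xi_warm <- NULL
  log_marginal <- function(theta) {
    sd_field <- exp(theta[1]); range <- exp(theta[2]); sd_unit <- exp(theta[3])
    P <- prec_matrix(sd_field, range, sd_unit)
    fit <- pois_newton(C, y, offset, P, init = xi_warm)
    xi_warm <<- fit$xi
    # Laplace: l(xi) - xi'Pxi/2 + logdet(P)/2 - logdet(H)/2, plus weak
    # hyperpriors (exponential on the SDs, lognormal on the range), with
    # log-scale Jacobians.
    lp_hyper <- (-sd_field + log(sd_field)) + (-sd_unit + log(sd_unit)) +
      stats::dlnorm(range, log(diag_extent / 4), 1, log = TRUE) + log(range)
    fit$objective + 0.5 * log_det_chol(P) - 0.5 * log_det_chol(fit$H) +
      lp_hyper
  }

  if (is.null(hyper)) {
    theta0 <- log(c(0.5, diag_extent / 5, 0.3))
    opt <- optim(theta0, function(th) -log_marginal(th),
                 method = "Nelder-Mead",
                 control = list(maxit = 80, reltol = 1e-4))
    theta <- opt$par
  } else {
    theta <- log(c(hyper[["sd_field"]], hyper[["range"]], hyper[["sd_unit"]]))
  }
  sd_field <- exp(theta[1]); range <- exp(theta[2]); sd_unit <- exp(theta[3])
  P <- prec_matrix(sd_field, range, sd_unit)
  fit <- pois_newton(C, y, offset, P, init = xi_warm)

  M <- solve(fit$H, t(C))
  eta <- drop(C %*% fit$xi)
  eta_sd <- sqrt(pmax(colSums(t(C) * M), 0))
  units <- tibble(
    unit_id = data$unit_id, lon = data$lon, lat = data$lat,
    deaths = data$deaths, expected = data$expected,
    log_rr = eta, log_rr_sd = eta_sd,
    rr = exp(eta),
    rr_lower = exp(eta - 1.96 * eta_sd),
    rr_upper = exp(eta + 1.96 * eta_sd))

  structure(
    list(units = units, xi = fit$xi, H = fit$H,
         hyper = c(sd_field = sd_field, range = range, sd_unit = sd_unit),
         covariates = covariates, centre = ctr, scale = scl,
         knot_axes = list(gx = gx, gy = gy), n_knots = K, n_units = n,
         prior_sd_coef = prior_sd_coef,
         coef = if (p > 0) setNames(fit$xi[seq_len(p)], covariates)
                else setNames(numeric(0), character(0))),
    class = "geo_rr_fit")
}

#' @export
print.geo_rr_fit <- function(x, ...) {
  cat("<geo_rr_fit>", x$n_units, "units,", x$n_knots, "spatial knots\n")
  cat(sprintf("  field sd %.3f, range %.2f deg, unit sd %.3f\n",
              x$hyper[["sd_field"]], x$hyper[["range"]], x$hyper[["sd_unit"]]))
  invisible(x)
}

#' Predict the smoothed relative-risk surface on a grid
#'
#' Posterior predictive relative risk per grid cell from the covariate
#' effects and the spatial field. Unit-level iid effects are excluded: they
#' are observation noise attached to survey units, not to places.
#'
#' @param fit A [fit_geostatistical_rr()] result.
#' @param grid Tibble with `lon`, `lat` and every covariate the model used
#'   (an error names any missing columns).
#' @return A `risk_surface` tibble: `lon`, `lat`, `rr`, `rr_lower`,
#'   `rr_upper`.
#' @export
predict_rr_grid <- function(fit, grid) {
  stopifnot(inherits(fit, "geo_rr_fit"))
  stopifnot_cols(grid, c("lon", "lat"), "grid")
  missing <- setdiff(fit$covariates, names(grid))
  if (length(missing) > 0) {
    abort(sprintf("Grid is missing covariate column(s): %s",
                  paste(missing, collapse = ", ")),
          class = "snakeburden_shape_error")
  }
  p <- length(fit$covariates)
  Xg <- if (p > 0) {
    sweep(sweep(as.matrix(grid[, fit$covariates, drop = FALSE]), 2,
                fit$centre), 2, fit$scale, "/")
  } else matrix(0, nrow(grid), 0)
  Ag <- bilinear_basis(grid$lon, grid$lat, fit$knot_axes$gx, fit$knot_axes$gy)
  Cg <- cbind(Xg, Ag, matrix(0, nrow(grid), fit$n_units))
  eta <- drop(Cg %*% fit$xi)
  M <- solve(fit$H, t(Cg))
  eta_sd <- sqrt(pmax(colSums(t(Cg) * M), 0))
  out <- tibble(lon = grid$lon, lat = grid$lat,
                rr = exp(eta),
                rr_lower = exp(eta - 1.96 * eta_sd),
                rr_upper = exp(eta + 1.96 * eta_sd))
  class(out) <- c("risk_surface", class(out))
  out
}

#' Convert a relative-risk surface to absolute risk before age 70
#'
#' Cellwise multiplication of the smoothed relative risks by the national
#' cumulative risk of snakebite death before age 70, with exceedance flags
#' at the 0.6% and 1% absolute-risk thresholds.
#'
#' @param surface A [predict_rr_grid()] result.
#' @param national_risk_pct National risk before 70 in percent, in (0, 100).
#' @return The surface with `abs_risk_pct` (+ `abs_risk_lower`/`_upper` when
#'   credible bounds are present) and logical `exceeds_0_6`, `exceeds_1`.
#' @export
absolute_risk <- function(surface, national_risk_pct) {
  stopifnot_cols(surface, c("lon", "lat", "rr"), "surface")
  if (!is.numeric(national_risk_pct) || national_risk_pct <= 0 ||
      national_risk_pct >= 100) {
    abort("`national_risk_pct` must be in (0, 100).",
          class = "snakeburden_validation_error")
  }
  out <- surface |>
    mutate(abs_risk_pct = .data$rr * national_risk_pct,
           exceeds_0_6 = .data$abs_risk_pct >= 0.6,
           exceeds_1 = .data$abs_risk_pct >= 1)
  if (all(c("rr_lower", "rr_upper") %in% names(surface))) {
    out <- mutate(out,
                  abs_risk_lower = .data$rr_lower * national_risk_pct,
                  abs_risk_upper = .data$rr_upper * national_risk_pct)
  }
  if (!inherits(out, "risk_surface")) {
    class(out) <- c("risk_surface", class(out))
  }
  out
}

#' Population living above absolute-risk thresholds
#'
#' Sums a co-registered population grid over the cells whose absolute risk
#' meets each threshold. The two grids must share identical cell centres; no
#' silent resampling is performed.
#'
#' @param surface An [absolute_risk()] result (needs `abs_risk_pct`).
#' @param population Tibble `lon`, `lat`, `population` on the same grid.
#' @param thresholds Absolute-risk thresholds in percent.
#' @return Tibble `threshold`, `population`, `share` (of total grid
#'   population).
#' @export
population_at_risk <- function(surface, population,
                               thresholds = c(0.6, 1)) {
  stopifnot_cols(surface, c("lon", "lat", "abs_risk_pct"), "surface")
  stopifnot_cols(population, c("lon", "lat", "population"), "population")
  s <- arrange(as_tibble(surface), .data$lon, .data$lat)
  g <- arrange(population, .data$lon, .data$lat)
  if (nrow(s) != nrow(g) ||
      max(abs(s$lon - g$lon), abs(s$lat - g$lat)) > 1e-8) {
    abort("Surface and population grids are not co-registered; resample explicitly before calling.",
          class = "snakeburden_grid_mismatch")
  }
  total <- sum(g$population)
  tibble(threshold = thresholds,
         population = vapply(thresholds, function(t)
           sum(g$population[s$abs_risk_pct >= t]), numeric(1))) |>
    mutate(share = .data$population / total)
}

#' Aggregate snakebite deaths to sampling units
#'
#' Counts included snakebite deaths per unit (ages 0-69 by default), giving
#' the observed counts for [fit_geostatistical_rr()].
#'
#' @param classified Output of [classify_records()].
#' @param units Unit table (`unit_id` plus any covariates to carry along).
#' @param max_age Upper age limit (exclusive, default 70).
#' @return `units` with a `deaths` count column.
#' @export
unit_death_counts <- function(classified, units, max_age = 70) {
  stopifnot_cols(classified, c("unit_id", "is_snakebite", "age"),
                 "classified")
  d <- classified |>
    filter(.data$is_snakebite, .data$age < max_age) |>
    count(.data$unit_id, name = "deaths")
  units |>
    left_join(d, by = "unit_id") |>
    mutate(deaths = tidyr::replace_na(.data$deaths, 0L))
}

#' Build a prediction grid with covariates taken from the nearest unit
#'
#' Constructs a regular lon/lat grid over the units' extent and fills each
#' cell's covariates (and optionally population) from the nearest sampling
#' unit, for use with [predict_rr_grid()] and [population_at_risk()].
#'
#' @param units Unit tibble with `lon`, `lat` and the covariate columns.
#' @param covariates Covariate columns to transfer.
#' @param nx,ny Grid resolution.
#' @return Tibble `lon`, `lat`, covariates, and `population` (each unit's
#'   population assigned to its nearest cell; cells may be zero).
#' @export
make_prediction_grid <- function(units, covariates = character(),
                                 nx = 25, ny = 25) {
  stopifnot_cols(units, c("lon", "lat", "population", covariates), "units")
  bb <- c(lon_min = min(units$lon), lon_max = max(units$lon),
          lat_min = min(units$lat), lat_max = max(units$lat))
  grid <- grid_centres(bb, nx, ny)
  D <- outer(grid$lon, units$lon, "-")^2 + outer(grid$lat, units$lat, "-")^2
  nearest <- max.col(-D)
  for (v in covariates) grid[[v]] <- units[[v]][nearest]
  cell_of_unit <- max.col(-t(D))
  pop <- tapply(units$population, cell_of_unit, sum)
  grid$population <- 0
  grid$population[as.integer(names(pop))] <- as.numeric(pop)
  grid
}
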