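# National Bayesian Poisson rates and the geostatistical relative-risk
# model: calibration, recovery, prediction and population at risk.

test_that("a single cell concentrates near its crude rate", {
  d <- tibble::tibble(age_band = "30-34", sex = "male", year = 2010,
                      deaths = 10, person_years = 2e5)
  fit <- fit_national_rates(d)
  expect_rel(fit$rates$rate, 5, 0.05)
  # doubling the offsets halves the posterior rates
  d2 <- dplyr::mutate(d, person_years = person_years * 2)
  fit2 <- fit_national_rates(d2)
  expect_rel(fit2$rates$rate, fit$rates$rate / 2, 0.01)
})

test_that("zero-exposure cells are dropped with a warning", {
  d <- tibble::tibble(age_band = c("0-4", "5-9"), sex = "male", year = 2010,
                      deaths = c(3, 0), person_years = c(1e5, 0))
  expect_warning(fit <- fit_national_rates(d), "zero exposure")
  expect_equal(nrow(fit$rates), 1)
})

test_that("the annual trend is covered by its credible interval", {
  covered <- 0
  for (seed in 1:10) {
    cfg <- sim_config(n_units = 150, seed = 1000 + seed,
                      mean_unit_population = 6000, annual_trend = -0.008,
                      spatial_sd = 0, other_death_rate = 0)
    w <- small_world(cfg)
    cl <- classify_records(w$deaths, review_from_truth(w$deaths))
    fit <- fit_national_rates(national_rate_input(cl, w$population,
                                                  cfg$years))
    if (fit$trend$lower <= -0.008 && -0.008 <= fit$trend$upper)
      covered <- covered + 1
  }
  expect_gte(covered, 8)
})

geo_world <- function(cfg, surface_mod = identity) {
  u <- generate_units(cfg)
  pop <- generate_population(u, cfg)
  s <- surface_mod(generate_true_surface(u, cfg))
  d <- generate_deaths(u, pop, s, cfg)
  cl <- classify_records(d, review_from_truth(d))
  nf <- fit_national_rates(national_rate_input(cl, pop, cfg$years))
  gd <- unit_death_counts(cl, u) |>
    dplyr::left_join(unit_expected_deaths(pop, nf, cfg$years),
                     by = "unit_id")
  list(units = u, population = pop, surface = s, data = gd)
}

test_that("a null world yields relative risks near one", {
  cfg <- sim_config(n_units = 200, seed = 51, years = 2004:2013,
                    mean_unit_population = 20000, spatial_sd = 0,
                    covariate_effects = list(), other_death_rate = 0)
  gw <- geo_world(cfg)
  fit <- fit_geostatistical_rr(gw$data, knots = c(6, 6))
  expect_gte(mean(fit$units$rr >= 0.9 & fit$units$rr <= 1.1), 0.95)
  # flat prediction grid
  grid <- make_prediction_grid(gw$units, nx = 10, ny = 10)
  surf <- predict_rr_grid(fit, grid)
  expect_true(all(surf$rr > 0.85 & surf$rr < 1.15))
})

test_that("field hyperparameters are recovered to order of magnitude", {
  cfg <- sim_config(n_units = 300, seed = 61, years = 2004:2013,
                    mean_unit_population = 20000, spatial_sd = 0.8,
                    spatial_range = 5, covariate_effects = list(),
                    other_death_rate = 0)
  gw <- geo_world(cfg)
  fit <- fit_geostatistical_rr(gw$data, knots = c(7, 7))
  expect_gt(fit$hyper[["sd_field"]], 0.8 / 2.5)
  expect_lt(fit$hyper[["sd_field"]], 0.8 * 2.5)
  expect_gt(fit$hyper[["range"]], 5 / 4)
  expect_lt(fit$hyper[["range"]], 5 * 4)
  # the latent field itself is tracked
  truth <- gw$surface$units$log_rr
  expect_gt(cor(truth, log(fit$units$rr)), 0.7)
})

test_that("prediction at a unit location approaches its smoothed RR as the nugget vanishes", {
  cfg <- sim_config(n_units = 120, seed = 71, years = 2004:2013,
                    mean_unit_population = 20000, spatial_sd = 0.5,
                    covariate_effects = list(), other_death_rate = 0)
  gw <- geo_world(cfg)
  hyper <- list(sd_field = 0.5, range = 4, sd_unit = 1e-4)
  fit <- fit_geostatistical_rr(gw$data, hyper = hyper)
  at_units <- tibble::tibble(lon = gw$data$lon, lat = gw$data$lat)
  pred <- predict_rr_grid(fit, at_units)
  expect_lt(max(abs(log(pred$rr) - log(fit$units$rr))), 0.02)
})

test_that("posterior RR is invariant to joint exposure scaling", {
  cfg <- sim_config(n_units = 80, seed = 81, years = 2004:2013,
                    mean_unit_population = 20000, spatial_sd = 0.4,
                    covariate_effects = list(), other_death_rate = 0)
  gw <- geo_world(cfg)
  hyper <- list(sd_field = 0.4, range = 4, sd_unit = 0.1)
  f1 <- fit_geostatistical_rr(gw$data, hyper = hyper)
  scaled <- dplyr::mutate(gw$data, deaths = deaths * 5,
                          expected = expected * 5)
  f2 <- fit_geostatistical_rr(scaled, hyper = hyper)
  expect_lt(median(abs(log(f2$units$rr) - log(f1$units$rr))), 0.1)
})

test_that("covariate and grid validation errors are informative", {
  cfg <- sim_config(n_units = 30, seed = 91, other_death_rate = 0)
  gw <- geo_world(cfg)
  bad <- gw$data
  bad$altitude_m[3] <- NaN
  expect_error(fit_geostatistical_rr(bad, covariates = "altitude_m"),
               bad$unit_id[3], class = "snakeburden_validation_error")
  fit <- fit_geostatistical_rr(gw$data, covariates = "altitude_m",
                               hyper = list(sd_field = 0.3, range = 4,
                                            sd_unit = 0.1))
  expect_error(predict_rr_grid(fit, tibble::tibble(lon = 70, lat = 20)),
               "altitude_m", class = "snakeburden_shape_error")
})

test_that("absolute risk scales relative risk by one constant", {
  surf <- tibble::tibble(lon = c(70, 71, 72), lat = 20,
                         rr = c(1, 1.5, 2.5),
                         rr_lower = c(0.8, 1.2, 2),
                         rr_upper = c(1.2, 1.8, 3))
  a <- absolute_risk(surf, 0.4)
  expect_equal(a$abs_risk_pct, c(0.4, 0.6, 1.0))
  expect_equal(a$exceeds_0_6, c(FALSE, TRUE, TRUE))
  expect_equal(a$exceeds_1, c(FALSE, FALSE, TRUE))
  # ratios of absolute risks equal ratios of RRs
  expect_equal(a$abs_risk_pct[3] / a$abs_risk_pct[1], surf$rr[3] / surf$rr[1])
  expect_error(absolute_risk(surf, 0), class = "snakeburden_validation_error")
})

test_that("population at risk sums thresholded cells exactly", {
  surf <- tibble::tibble(lon = rep(1:10, each = 10), lat = rep(1:10, 10),
                         rr = 1, abs_risk_pct = rep(c(2, 0.4), c(10, 90)))
  pop <- tibble::tibble(lon = surf$lon, lat = surf$lat, population = 100)
  par <- population_at_risk(surf, pop, thresholds = c(0, 1, 99))
  expect_equal(par$population, c(10000, 1000, 0))
  expect_equal(par$share, c(1, 0.1, 0))
  expect_true(all(diff(par$population) <= 0))
  # mismatched grids refuse to resample silently
  pop2 <- pop
  pop2$lon[1] <- pop2$lon[1] + 0.5
  expect_error(population_at_risk(surf, pop2),
               class = "snakeburden_grid_mismatch")
})
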