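# The synthetic-data generator: determinism, calibration against analytic
# expectations, and null structure when effects are switched off.

test_that("unit generation honours the config and is deterministic", {
  cfg <- tiny_config(n_units = 25, seed = 7)
  u1 <- generate_units(cfg)
  u2 <- generate_units(cfg)
  expect_identical(u1, u2)
  expect_equal(nrow(u1), 25)
  bb <- cfg$bbox
  expect_true(all(u1$lon >= bb[["lon_min"]] & u1$lon <= bb[["lon_max"]]))
  expect_true(all(u1$lat >= bb[["lat_min"]] & u1$lat <= bb[["lat_max"]]))
  expect_true(all(u1$population > 0))
  expect_true(all(u1$altitude_m > 0))
  expect_true(all(u1$female_illiteracy >= 0 & u1$female_illiteracy <= 1))
  pop <- generate_population(u1, cfg)
  expect_true(all(pop$population > 0))
  expect_equal(sum(pop$population), sum(u1$population))

  w <- small_world(tiny_config(n_units = 10, seed = 3))
  w2 <- small_world(tiny_config(n_units = 10, seed = 3))
  expect_identical(w$deaths, w2$deaths)
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(n_units = 1), "n_units",
               class = "snakeburden_config_error")
  expect_error(sim_config(n_units = 10, base_rate = 0), "base_rate",
               class = "snakeburden_config_error")
  expect_error(sim_config(n_units = 10, spatial_range = -1), "spatial_range",
               class = "snakeburden_config_error")
  expect_error(sim_config(n_units = 10, coder_agreement = 1.2),
               "coder_agreement", class = "snakeburden_config_error")
  expect_error(sim_config(n_units = 10, seasonal_amplitude = -0.1),
               "seasonal_amplitude", class = "snakeburden_config_error")
})

test_that("rural population share tracks the configured share", {
  cfg <- sim_config(n_units = 5000, seed = 9, rural_share = 0.94)
  u <- generate_units(cfg)
  share <- weighted.mean(u$rural, u$population)
  expect_lt(abs(share - 0.94), 0.01)
})

test_that("true surface has population-weighted mean RR 1 and a seasonal curve of mean 1", {
  w <- small_world(tiny_config(n_units = 60, seed = 12, spatial_sd = 0.5))
  rr <- exp(w$surface$units$log_rr)
  expect_equal(weighted.mean(rr, w$units$population), 1, tolerance = 1e-10)
  expect_equal(mean(w$surface$seasonal$multiplier), 1, tolerance = 1e-12)
  # null structure: no spatial effect -> flat field
  w0 <- small_world(tiny_config(n_units = 30, seed = 12, spatial_sd = 0))
  expect_true(all(w0$surface$units$log_rr == 0))
  s0 <- generate_true_surface(w0$units,
                              tiny_config(n_units = 30, seed = 12,
                                          seasonal_amplitude = 0))
  expect_true(all(s0$seasonal$multiplier == 1))
})

test_that("death counts match the Poisson expectation at RR 1", {
  # 1M persons x 10 years = 10M person-years at 4.8/100k -> ~480 deaths
  cfg <- sim_config(n_units = 500, seed = 17, years = 2004:2013,
                    mean_unit_population = 2000, spatial_sd = 0,
                    covariate_effects = list(), other_death_rate = 0)
  w <- small_world(cfg)
  expected <- sum(true_expected_deaths(w$units, w$population, w$surface,
                                       cfg)$expected)
  py <- sum(w$units$population) * 10
  expect_rel(expected, py * 4.8e-5, 0.02)
  observed <- nrow(w$deaths)
  expect_lt(abs(observed - expected), 3 * sqrt(expected))
})

test_that("flat seasonality gives uniform death dates", {
  cfg <- sim_config(n_units = 300, seed = 23, years = 2004:2013,
                    mean_unit_population = 7000, base_rate = 50,
                    seasonal_amplitude = 0, spatial_sd = 0,
                    covariate_effects = list(), other_death_rate = 0)
  w <- small_world(cfg)
  expect_gt(nrow(w$deaths), 8000)
  months <- lubridate::month(w$deaths$date_of_death)
  days_in_month <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  gof <- suppressWarnings(
    stats::chisq.test(tabulate(months, 12), p = days_in_month / 365))
  expect_gt(gof$p.value, 0.01)
})

test_that("dual-coder agreement matches the configured probability", {
  cfg <- sim_config(n_units = 400, seed = 29, mean_unit_population = 5000,
                    spatial_sd = 0, other_death_rate = 0)
  w <- small_world(cfg)
  snake <- w$deaths[w$deaths$cause_true == "snakebite", ]
  expect_gt(nrow(snake), 1000)
  agree <- mean(snake$coder2_icd10 == "X20")
  expect_lt(abs(agree - 0.92), 0.02)
  expect_true(all(snake$coder1_icd10 == "X20"))
  expect_true(all(snake$coder2_icd10 %in% c("X20", "X27", "X29")))
})

test_that("misaligned surface raises an alignment error", {
  w <- small_world(tiny_config(n_units = 10, seed = 1))
  surf <- w$surface
  surf$units <- surf$units[-1, ]
  expect_error(
    generate_deaths(w$units, w$population, surf, w$config),
    class = "snakeburden_alignment_error")
})

test_that("literature studies are calibrated and overdisperse on demand", {
  st <- generate_literature_studies(78, true_cfr = 0.032, dispersion = 0,
                                    seed = 4)
  use <- st[!is.na(st$bites), ]
  pooled <- sum(use$deaths) / sum(use$bites)
  expect_lt(abs(pooled - 0.032), 0.005)

  z <- generate_literature_studies(20, true_cfr = 0, seed = 2)
  expect_true(all(z$deaths[!is.na(z$bites)] == 0))

  lo <- generate_literature_studies(300, 0.05, dispersion = 0, seed = 6)
  hi <- generate_literature_studies(300, 0.05, dispersion = 0.05, seed = 6)
  vlo <- var((lo$deaths / lo$bites)[!is.na(lo$bites)])
  vhi <- var((hi$deaths / hi$bites)[!is.na(hi$bites)])
  expect_gt(vhi, 2 * vlo)

  expect_error(generate_literature_studies(2, 0.03),
               class = "snakeburden_insufficient_data")
})
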