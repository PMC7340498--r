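# Cause fractions, smoothing, envelope scaling, standardization, risk
# before 70, spline trends and hospital splits.

frac_tbl <- function(years, num, den) {
  tibble::tibble(year = years, weighted_snakebite = num,
                 weighted_total = den, n_snakebite = num, n_total = den,
                 fraction = ifelse(den > 0, num / den, NA_real_))
}

test_that("weighted fractions match hand arithmetic", {
  recs <- tibble::tibble(
    is_snakebite = c(rep(TRUE, 2), rep(FALSE, 98)),
    sampling_weight = 1,
    year = 2010)
  expect_equal(weighted_fractions(recs)$fraction, 0.02)

  recs2 <- tibble::tibble(is_snakebite = c(TRUE, FALSE),
                          sampling_weight = c(3, 1), year = 2010)
  expect_equal(weighted_fractions(recs2)$fraction, 0.75)

  recs2$sampling_weight[1] <- 0
  expect_error(weighted_fractions(recs2),
               class = "snakeburden_validation_error")
})

test_that("pooled study counts give the published national fraction", {
  yearly <- mds_yearly_estimates()
  recs <- tibble::tibble(
    is_snakebite = c(rep(TRUE, sum(yearly$study_snakebite_deaths)),
                     rep(FALSE, sum(yearly$study_all_cause_deaths) -
                           sum(yearly$study_snakebite_deaths))),
    sampling_weight = 1, period = "2001-2014")
  f <- weighted_fractions(recs, by = "period")
  expect_equal(f$n_total, 611483)
  expect_equal(f$fraction, 2833 / 611483)
  expect_equal(round(100 * f$fraction, 2), 0.46)
})

test_that("moving average smooths counts, not ratios, and respects edges", {
  t1 <- frac_tbl(2001:2005, num = rep(2, 5), den = rep(100, 5))
  expect_equal(moving_average(t1)$fraction, rep(0.02, 5))

  t2 <- frac_tbl(2001:2003, num = c(1, 2, 3), den = rep(100, 3))
  ma <- moving_average(t2)
  expect_equal(ma$fraction[3], 0.02)       # mean of three
  expect_equal(ma$fraction[1], 0.01)       # first year = own value
  expect_equal(ma$fraction[2], 0.015)      # two-year renormalized window

  expect_error(moving_average(t2, lag_weights = c(1, -1, 1)),
               class = "snakeburden_config_error")
  # smoothing never produces negative fractions
  set.seed(1)
  t3 <- frac_tbl(2001:2010, num = rpois(10, 3), den = rpois(10, 200) + 1)
  expect_true(all(moving_average(t3)$fraction >= 0))
})

test_that("zero strata are interpolated linearly with edge carry", {
  t1 <- frac_tbl(2001:2003, num = c(2, 0, 4), den = c(100, 0, 100))
  out <- interpolate_zero_strata(t1)
  expect_equal(out$fraction[2], 0.03)
  expect_true(out$imputed[2])

  t2 <- frac_tbl(2001:2003, num = c(0, 2, 3), den = c(0, 100, 100))
  out2 <- interpolate_zero_strata(t2)
  expect_equal(out2$fraction[1], 0.02)     # carried back from nearest year

  t3 <- frac_tbl(2001:2003, num = c(1, 2, 3), den = rep(100, 3))
  out3 <- interpolate_zero_strata(t3)
  expect_equal(out3$fraction, t3$fraction)
  expect_false(any(out3$imputed))

  t4 <- frac_tbl(2001:2002, num = c(0, 0), den = c(0, 0))
  expect_warning(out4 <- interpolate_zero_strata(t4), "left missing")
  expect_true(all(is.na(out4$fraction)))
})

test_that("envelope scaling is exact and conserves the envelope", {
  t1 <- frac_tbl(2010, 50, 10000)
  t1$fraction <- 0.005
  env <- tibble::tibble(year = 2010, total_deaths = 1e7)
  expect_equal(scale_to_envelope(t1, env)$estimated_deaths, 50000)

  t0 <- frac_tbl(2010, 0, 100)
  expect_equal(scale_to_envelope(t0, env)$estimated_deaths, 0)

  expect_error(scale_to_envelope(frac_tbl(2011, 1, 10), env), "2011",
               class = "snakeburden_validation_error")

  # conservation: cause fractions partitioning 1 reproduce the envelope
  set.seed(2)
  for (i in 1:5) {
    k <- sample(3:6, 1)
    f <- runif(k); f <- f / sum(f)
    tab <- tibble::tibble(year = 2010, cause = paste0("c", 1:k), fraction = f)
    scaled <- scale_to_envelope(tab, env)
    expect_equal(sum(scaled$estimated_deaths), env$total_deaths)
  }
})

test_that("age standardization is a normalized weighted mean", {
  r <- tibble::tibble(age_band = c("0-4", "5-9"), rate = c(2, 6))
  std <- tibble::tibble(age_band = c("0-4", "5-9"), weight = c(0.25, 0.75))
  expect_equal(age_standardize(r, std)$standardized_rate, 5)
  std2 <- dplyr::mutate(std, weight = weight * 2)
  expect_equal(age_standardize(r, std2)$standardized_rate, 5)

  rc <- tibble::tibble(age_band = india_standard_population()$age_band,
                       rate = 5)
  expect_equal(age_standardize(rc)$standardized_rate, 5)

  expect_error(age_standardize(
    tibble::tibble(age_band = "0-4", rate = 1),
    tibble::tibble(age_band = "5-9", weight = 1)),
    "0-4", class = "snakeburden_alignment_error")
})

test_that("risk before 70 is the additive band sum", {
  expect_equal(risk_before_70(rep(0, 14)), 0)
  expect_equal(risk_before_70(rep(5, 14)), 0.35)
  # broad-band reconstruction: 3 bands at 4.5, 3 at 3.1, 8 at 5.8
  broad <- c(rep(4.5, 3), rep(3.1, 3), rep(5.8, 8))
  expect_equal(risk_before_70(broad), 0.346)
  expect_error(risk_before_70(rep(5, 13)),
               class = "snakeburden_validation_error")
  # tibble interface agrees with the vector interface
  tb <- tibble::tibble(age_band = bands <- sprintf("%d-%d", seq(0, 65, 5),
                                                   seq(0, 65, 5) + 4),
                       rate = broad)
  expect_equal(risk_before_70(tb), 0.346)
})

test_that("spline trend reproduces polynomials and extrapolates linearly", {
  lin <- tibble::tibble(year = 2003:2014, value = 3 + 0.5 * (2003:2014 - 2003))
  st <- spline_trend(lin, predict_years = 2000:2019)
  expect_equal(st$fitted, 3 + 0.5 * (st$year - 2003), tolerance = 1e-8)
  expect_setequal(st$source[st$year %in% c(2000, 2015:2019)], "extrapolated")

  const <- tibble::tibble(year = 2003:2014, value = 4.2)
  stc <- spline_trend(const, predict_years = 2000:2019)
  expect_equal(stc$fitted, rep(4.2, 20), tolerance = 1e-8)

  yrs <- 2003:2014
  cub <- 2 + 0.3 * (yrs - 2008) - 0.05 * (yrs - 2008)^2 + 0.01 * (yrs - 2008)^3
  stq <- spline_trend(tibble::tibble(year = yrs, value = cub))
  expect_lt(max(abs(stq$fitted - cub)), 1e-6)

  expect_error(spline_trend(lin[1:5, ], knots = 3), "reduce",
               class = "snakeburden_config_error")
})

test_that("hospital split partitions totals exactly", {
  s <- hospital_split(759.4, 154.2 / 759.4)
  expect_equal(s$in_hospital, 154.2)
  expect_equal(s$in_hospital + s$out_of_hospital, 759.4)
  expect_equal(hospital_split(100, 0)$in_hospital, 0)
  s2 <- hospital_split(100, 0.23)
  expect_equal(c(s2$in_hospital, s2$out_of_hospital), c(23, 77))
  expect_error(hospital_split(1, 1.2), class = "snakeburden_validation_error")
})

test_that("national totals, standardized rate and risk-70 are recovered from a 10k-death world", {
  cfg <- sim_config(n_units = 500, seed = 31, mean_unit_population = 3e4,
                    other_death_rate = 5e-4)
  w <- small_world(cfg)
  cl <- classify_records(w$deaths, review_from_truth(w$deaths))
  expect_gt(sum(cl$is_snakebite), 9000)

  truth <- sum(true_expected_deaths(w$units, w$population, w$surface,
                                    cfg)$expected)
  est <- weighted_fractions(cl) |>
    moving_average() |>
    interpolate_zero_strata() |>
    scale_to_envelope(make_envelope(w$deaths))
  expect_rel(sum(est$estimated_deaths), truth, 0.05)

  pb <- w$population |>
    dplyr::mutate(age_band = as.character(age_band)) |>
    dplyr::group_by(age_band) |>
    dplyr::summarise(population = sum(population), .groups = "drop")
  br <- cl |>
    dplyr::filter(is_snakebite) |>
    dplyr::mutate(age_band = as.character(cut_age_band(age))) |>
    dplyr::count(age_band, name = "deaths") |>
    dplyr::right_join(pb, by = "age_band") |>
    dplyr::mutate(deaths = tidyr::replace_na(deaths, 0L),
                  rate = deaths / population / length(cfg$years) * 1e5)
  sr <- age_standardize(br[, c("age_band", "rate")])
  expect_rel(sr$standardized_rate, cfg$base_rate, 0.05)

  r70 <- risk_before_70(br[br$age_band %in%
                             sprintf("%d-%d", seq(0, 65, 5),
                                     seq(0, 65, 5) + 4),
                           c("age_band", "rate")])
  expect_rel(r70, true_risk70(cfg$base_rate), 0.10)
})
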