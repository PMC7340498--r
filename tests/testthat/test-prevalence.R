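# Case-fatality regression and indirect bite/envenomation back-calculation.

test_that("an exact proportional table gives the exact slope", {
  st <- tibble::tibble(study_id = paste0("s", 1:10), study_type = "hospital",
                       bites = seq(100, 1000, 100))
  st$deaths <- 0.05 * st$bites
  fit <- suppressWarnings(estimate_cfr(st))  # lm warns on a perfect fit
  expect_equal(fit$cfr, 0.05, tolerance = 1e-12)
  expect_equal(nrow(fit$excluded), 0)
})

test_that("synthetic studies at 3.2% CFR are recovered", {
  st <- generate_literature_studies(78, true_cfr = 0.032, dispersion = 0.002,
                                    seed = 5)
  fit <- estimate_cfr(st)
  expect_gt(fit$cfr, 0.027)
  expect_lt(fit$cfr, 0.037)
})

test_that("a planted outlier is flagged, removed, and the slope restored", {
  st <- generate_literature_studies(20, true_cfr = 0.03, dispersion = 0,
                                    seed = 8, outlier_fraction = 0.05,
                                    outlier_cfr = 0.5, autopsy_fraction = 0)
  fit <- estimate_cfr(st)
  expect_equal(nrow(fit$excluded), 1)
  expect_gt(fit$excluded$deaths / fit$excluded$bites, 0.3)
  expect_lt(abs(fit$cfr - 0.03), 0.005)
})

test_that("the through-origin estimator is unbiased on clean data", {
  slopes <- vapply(1:100, function(s) {
    st <- generate_literature_studies(30, 0.04, dispersion = 0, seed = s,
                                      autopsy_fraction = 0)
    estimate_cfr(st)$cfr
  }, numeric(1))
  se <- sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes) - 0.04), 2 * se + 1e-4)
})

test_that("degenerate study tables raise estimation errors", {
  st <- tibble::tibble(study_id = c("a", "b"), study_type = "hospital",
                       bites = c(10, 20), deaths = c(1, 1))
  expect_error(estimate_cfr(st), class = "snakeburden_estimation_error")
  st2 <- tibble::tibble(study_id = "a", study_type = "hospital",
                        bites = 10, deaths = 12)
  st2 <- dplyr::bind_rows(st2, st2, st2)
  expect_error(estimate_cfr(st2), class = "snakeburden_validation_error")
})

test_that("in-hospital prevalence back-calculates deaths / CFR", {
  expect_equal(inhospital_prevalence(3200, 0.032), 100000)
  expect_equal(inhospital_prevalence(0, 0.05), 0)
  expect_error(inhospital_prevalence(100, 0),
               class = "snakeburden_validation_error")
  # ambulance cohort: 359 deaths at 1.3% implies ~27,600 transported
  amb <- ambulance_cohort_2014()
  implied <- inhospital_prevalence(amb$deaths, 0.013)
  expect_rel(implied, amb$transported, 0.005)
})

test_that("scenario totals, ranges and monotonicity", {
  one <- tibble::tibble(hospital_deaths = 5e5 * 0.032, cfr = 0.032,
                        out_to_in_ratio = 1, envenomation_share = 0.7)
  tb <- total_bites(one)
  expect_equal(tb$total_bites, 1e6)
  expect_equal(total_bites(dplyr::mutate(one, out_to_in_ratio = 0))$total_bites,
               5e5)
  # default scenarios bracket the published 1.11-1.77 million range
  def <- total_bites(default_prevalence_scenarios())
  rng <- attr(def, "range")
  expect_rel(rng[["min"]], 1.11e6, 0.005)
  expect_rel(rng[["max"]], 1.77e6, 0.005)
  # monotone in the out:in ratio and in 1/cfr
  base <- dplyr::mutate(one, out_to_in_ratio = 2)
  expect_gt(total_bites(base)$total_bites, tb$total_bites)
  lower_cfr <- dplyr::mutate(one, cfr = 0.016)
  expect_gt(total_bites(lower_cfr)$total_bites, tb$total_bites)
})

test_that("envenomation partition is exact and reproduces published bounds", {
  p <- partition_envenomation(c(1.77, 1.11) * 1e6)
  expect_equal(round(p$envenomations[1] / 1e6, 2), 1.24)
  expect_rel(p$envenomations[2] / 1e6, 0.77, 0.01)
  expect_equal(round(p$dry_bites / 1e6, 2), c(0.53, 0.33))
  expect_equal(p$envenomations + p$dry_bites, p$total)
  expect_equal(partition_envenomation(10, 1)$dry_bites, 0)
  expect_error(partition_envenomation(1, 1.5),
               class = "snakeburden_validation_error")
})
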