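# Published national summary tables from the Indian Million Death Study
# snakebite analyses. The unit-record survey data cannot be redistributed;
# these aggregate tables are the public inputs that the arithmetic
# operations (bounds, coverage, projections, envenomation splits) consume.

#' Yearly study deaths and national estimates, 2001-2014
#'
#' Published yearly Million Death Study snakebite counts: study deaths from
#' snakebite and from all causes, the age-standardized rate (2001 census
#' standard) and broad-band age-specific rates per 100,000, the cumulative
#' risk of snakebite death before age 70, and estimated national snakebite
#' deaths in thousands (cause fractions scaled to UN death totals).
#'
#' @return A tibble with one row per year 2001-2014.
#' @export
mds_yearly_estimates <- function() {
  tibble(
    year = 2001:2014,
    study_snakebite_deaths = c(199L, 183L, 179L, 190L, 244L, 214L, 225L,
                               215L, 183L, 200L, 185L, 227L, 214L, 175L),
    study_all_cause_deaths = c(41826L, 41740L, 38798L, 37380L, 46755L,
                               47471L, 48536L, 47673L, 47873L, 45719L,
                               46099L, 46635L, 45331L, 29647L),
    std_rate = c(5.3, 5.2, 5.1, 5.0, 4.9, 5.3, 5.3, 5.1, 4.7, 4.3, 4.2,
                 4.3, 4.6, 4.7),
    rate_0_14 = c(5.4, 5.2, 5.0, 4.6, 4.8, 4.7, 4.5, 4.2, 3.9, 3.9, 4.0,
                  4.3, 4.4, 4.2),
    rate_15_29 = c(3.6, 3.5, 3.4, 3.5, 3.4, 3.2, 3.0, 2.8, 2.6, 2.6, 2.7,
                   2.8, 3.0, 3.0),
    rate_30_69 = c(5.9, 5.8, 5.8, 5.7, 6.4, 6.7, 6.4, 5.9, 5.3, 5.0, 5.1,
                   5.4, 5.8, 5.9),
    risk_before_70_pct = c(0.40, 0.39, 0.38, 0.38, 0.40, 0.40, 0.39, 0.36,
                           0.33, 0.32, 0.33, 0.36, 0.38, 0.37),
    national_deaths_thousands = c(55.0, 55.3, 55.8, 55.6, 60.8, 62.7, 61.0,
                                  57.4, 53.8, 52.4, 54.9, 59.2, 62.3, 61.2))
}

#' Pooled 2001-2014 summary row
#'
#' Pooled study-period values: standardized and broad-band rates per
#' 100,000, risk before 70, and the 2001-2014 national death total with its
#' plausible range (thousands).
#'
#' @return A one-row tibble.
#' @export
mds_pooled_estimates <- function() {
  tibble(std_rate = 4.8, rate_0_14 = 4.5, rate_15_29 = 3.1, rate_30_69 = 5.8,
         risk_before_70_pct = 0.37,
         national_deaths_thousands = 807.5,
         national_deaths_lower = 738.2, national_deaths_upper = 833.4)
}

#' Spline-extrapolated annual national deaths outside the study period
#'
#' Annual national snakebite deaths in thousands for the years outside
#' 2001-2014, obtained by extrapolating the fitted trend: 2000 backward and
#' 2015-2019 forward.
#'
#' @return A tibble `year`, `national_deaths_thousands`.
#' @export
mds_projected_years <- function() {
  tibble(year = c(2000L, 2015L, 2016L, 2017L, 2018L, 2019L),
         national_deaths_thousands = c(54.0, 62.3, 62.0, 61.4, 60.3, 59.8))
}

#' Estimated 2000-2019 deaths by age and sex (thousands)
#'
#' Twenty-year national snakebite death estimates by broad age band and
#' sex, with lower/upper plausible bounds from single- versus dual-coder
#' agreement.
#'
#' @return A tibble `age_range`, `sex`, `deaths`, `lower`, `upper`.
#' @export
mds_age_sex_totals <- function() {
  tibble(
    age_range = rep(c("0-14", "15-29", "30-69", "70+"), each = 2),
    sex = rep(c("male", "female"), 4),
    deaths = c(149, 176, 109, 88, 290, 253, 54, 48),
    lower = c(134, 160, 102, 82, 269, 232, 45, 44),
    upper = c(154, 180, 111, 89, 303, 260, 60, 50))
}

#' Dual-coder review counts behind the plausible range
#'
#' The published adjudication of probable snakebite deaths: immediate
#' dual-coder X20 agreements, candidates where one coder gave X20 and the
#' other X27/X29 (with the number review-confirmed), and candidates where
#' one coder gave an X20/X27/X29 code against an unrelated code (none
#' confirmed).
#'
#' @return A tibble `pattern`, `n`, `n_confirmed`.
#' @export
mds_coding_review <- function() {
  tibble(pattern = c("dual_x20", "x20_vs_x27_x29", "snake_vs_other"),
         n = c(2779L, 105L, 136L),
         n_confirmed = c(2779L, 54L, 0L))
}

#' Expand the review counts into per-record form
#'
#' Reconstructs a record-level table (and matching review table) consistent
#' with the published review counts, so the dual-coder classification and
#' bounds operations can be exercised on the published totals: dual-X20
#' agreements, X20-vs-X27 candidates with the confirmed subset, and
#' X29-vs-other-code candidates (none confirmed).
#'
#' @param counts Output of [mds_coding_review()] (or the same shape).
#' @return A list with `records` and `review` tibbles ready for
#'   [classify_records()].
#' @export
coding_review_records <- function(counts = mds_coding_review()) {
  stopifnot_cols(counts, c("pattern", "n", "n_confirmed"), "counts")
  get <- function(p, col) counts[[col]][counts$pattern == p]
  n1 <- get("dual_x20", "n")
  n2 <- get("x20_vs_x27_x29", "n"); k2 <- get("x20_vs_x27_x29", "n_confirmed")
  n3 <- get("snake_vs_other", "n"); k3 <- get("snake_vs_other", "n_confirmed")
  records <- tibble(
    record_id = sprintf("R%04d", seq_len(n1 + n2 + n3)),
    coder1_icd10 = c(rep("X20", n1 + n2), rep("X29", n3)),
    coder2_icd10 = c(rep("X20", n1), rep("X27", n2), rep("R99", n3)))
  review <- tibble(
    record_id = records$record_id[(n1 + 1):(n1 + n2 + n3)],
    is_snakebite = c(rep(TRUE, k2), rep(FALSE, n2 - k2),
                     rep(TRUE, k3), rep(FALSE, n3 - k3)))
  list(records = records, review = review)
}

#' Government surveillance reports versus estimated deaths, 2003-2015
#'
#' Published per-state comparison inputs: government-reported snakebite
#' bites and deaths from public hospitals (thousands), the share of
#' estimated deaths occurring in hospital, and the estimated total and
#' in-hospital snakebite deaths (thousands). The `in_hospital_fraction`
#' column is the unrounded ratio of the published in-hospital to total
#' estimates, so the coverage arithmetic reproduces the published cells.
#'
#' @return A tibble with one row per state/region.
#' @export
gov_surveillance_2003_2015 <- function() {
  tbl <- tibble::tribble(
    ~region, ~reported_bites, ~reported_deaths, ~pct_died_in_hospital,
    ~est_total_deaths, ~est_hospital_deaths,
    "Andhra Pradesh", 251.3, 1.4, 16, 74.1, 11.6,
    "Bihar", 20.9, 0.1, 16, 105.4, 17.0,
    "Odisha", 76.2, 1.8, 29, 36.9, 10.9,
    "Madhya Pradesh", 28.3, 1.1, 22, 64.4, 14.1,
    "Uttar Pradesh", 27.8, 0.6, 13, 150.7, 20.2,
    "Rajasthan", 71.3, 1.0, 16, 49.6, 7.8,
    "Gujarat", 45.7, 0.8, 27, 38.6, 10.5,
    "Jharkhand", 8.5, 0.1, 12, 20.0, 2.5,
    "Chhattisgarh", 16.7, 0.3, 17, 14.3, 2.4,
    "Jammu & Kashmir", 18.4, 0.0, 26, 5.9, 1.5,
    "Tamil Nadu", 106.6, 0.5, 28, 36.0, 10.0,
    "Karnataka", 89.2, 1.6, 21, 28.1, 6.0,
    "Maharashtra", 178.7, 1.2, 25, 49.0, 12.5,
    "West Bengal", 208.9, 3.4, 41, 38.9, 15.9,
    "Punjab", 9.1, 0.2, 10, 14.2, 1.4,
    "Haryana", 14.3, 0.1, 16, 8.5, 1.3,
    "Assam", 3.6, 0.1, 32, 6.6, 2.1,
    "Northeastern states", 11.1, 0.1, 25, 1.8, 0.4,
    "Kerala", 37.9, 0.2, 27, 5.2, 3.5,
    "All other states", 77.8, 0.8, 24, 11.1, 2.7)
  mutate(tbl, in_hospital_fraction = .data$est_hospital_deaths /
           .data$est_total_deaths)
}

#' 2014 ambulance cohort
#'
#' Snakebite patients transported to hospital within six hours by a
#' state ambulance service in 2014 and their 48-hour deaths; the ratio is
#' the ambulance-cohort crude case-fatality rate.
#'
#' @return A one-row tibble `transported`, `deaths`.
#' @export
ambulance_cohort_2014 <- function() {
  tibble(transported = 27509L, deaths = 359L)
}

#' Published bite-total range for 2015
#'
#' The scenario-based range of total annual snakebites (millions) and the
#' envenomation share observed across hospital studies.
#'
#' @return A one-row tibble `total_bites_low_m`, `total_bites_high_m`,
#'   `envenomation_share`.
#' @export
bite_burden_constants <- function() {
  tibble(total_bites_low_m = 1.11, total_bites_high_m = 1.77,
         envenomation_share = 0.70)
}
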