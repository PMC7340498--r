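# Case-fatality regression on literature studies and indirect back-
# calculation of national bite and envenomation totals.

#' Estimate the case-fatality rate from literature studies
#'
#' Ordinary least squares of study deaths on study bites through the origin
#' (a study with zero bites must imply zero deaths); the slope is the crude
#' case-fatality rate. Extreme outliers are flagged by standardized residual
#' beyond `outlier_threshold` and removed in a single pass before refitting.
#' Autopsy-type studies (no bite denominator) are excluded up front.
#'
#' @param studies Tibble `study_id`, `study_type`, `bites`, `deaths`.
#' @param outlier_threshold Absolute standardized-residual cut (default 3).
#' @param intercept Fit a free intercept instead of regression through the
#'   origin? Default `FALSE`.
#' @return Object of class `cfr_fit`: list with `cfr` (slope), `se`,
#'   `ci` (95%), `excluded` (tibble of removed outliers), `n_used`,
#'   `model` (the refitted `lm`), `data` (studies used, with residual
#'   diagnostics).
#' @export
#' @examples
#' st <- generate_literature_studies(30, 0.032, seed = 1)
#' estimate_cfr(st)$cfr
estimate_cfr <- function(studies, outlier_threshold = 3, intercept = FALSE) {
  stopifnot_cols(studies, c("study_id", "bites", "deaths"), "studies")
  use <- studies |>
    filter(!is.na(.data$bites), !is.na(.data$deaths), .data$bites > 0)
  if (nrow(use) < 3) {
    abort("Fewer than 3 usable studies with both bites and deaths.",
          class = "snakeburden_estimation_error")
  }
  if (any(use$deaths > use$bites)) {
    abort("Found studies with more deaths than bites.",
          class = "snakeburden_validation_error")
  }
  form <- if (intercept) deaths ~ bites else deaths ~ 0 + bites
  fit0 <- lm(form, data = use)
  r <- rstandard(fit0)
  out <- abs(r) > outlier_threshold
  excluded <- use[out, ]
  use2 <- use[!out, ]
  if (nrow(use2) < 3) {
    abort("Outlier removal left fewer than 3 studies.",
          class = "snakeburden_estimation_error")
  }
  fit <- lm(form, data = use2)
  ci <- suppressMessages(confint(fit, "bites", level = 0.95))
  structure(
    list(cfr = unname(coef(fit)[["bites"]]),
         se = unname(sqrt(diag(vcov(fit)))[["bites"]]),
         ci = c(lower = ci[1], upper = ci[2]),
         excluded = excluded, n_used = nrow(use2),
         intercept = intercept, outlier_threshold = outlier_threshold,
         model = fit,
         data = mutate(use2, std_residual = rstandard(fit))),
    class = "cfr_fit")
}

#' @export
print.cfr_fit <- function(x, ...) {
  cat(sprintf("<cfr_fit> CFR %.4f [%.4f, %.4f] from %d studies (%d outlier(s) removed)\n",
              x$cfr, x$ci[["lower"]], x$ci[["upper"]], x$n_used,
              nrow(x$excluded)))
  invisible(x)
}

#' In-hospital bites implied by hospital deaths and a case-fatality rate
#'
#' @param hospital_deaths Estimated in-hospital snakebite deaths.
#' @param cfr Case-fatality rate in (0, 1].
#' @return Implied number of in-hospital bites (`deaths / cfr`).
#' @export
#' @examples
#' inhospital_prevalence(3200, 0.032) # 100000
inhospital_prevalence <- function(hospital_deaths, cfr) {
  if (any(cfr <= 0 | cfr > 1)) {
    abort("`cfr` must be in (0, 1].", class = "snakeburden_validation_error")
  }
  hospital_deaths / cfr
}

#' Total bites under explicit prevalence scenarios
#'
#' For each scenario, in-hospital bites are back-calculated as
#' `hospital_deaths / cfr` and total bites as in-hospital bites times
#' `(1 + out_to_in_ratio)`. The scenario assumptions are echoed in the
#' output for audit, and the min-max range over scenarios is attached as
#' attribute `"range"`.
#'
#' @param scenarios Tibble with `hospital_deaths`, `cfr`, `out_to_in_ratio`,
#'   `envenomation_share` (and optionally `scenario`, `year`).
#' @return The scenarios with `in_hospital_bites`, `total_bites`,
#'   `envenomations`, `dry_bites` added.
#' @export
total_bites <- function(scenarios) {
  stopifnot_cols(scenarios,
                 c("hospital_deaths", "cfr", "out_to_in_ratio",
                   "envenomation_share"), "scenarios")
  if (nrow(scenarios) == 0) {
    abort("Need at least one scenario.",
          class = "snakeburden_validation_error")
  }
  if (any(scenarios$out_to_in_ratio < 0)) {
    abort("`out_to_in_ratio` must be non-negative.",
          class = "snakeburden_validation_error")
  }
  out <- scenarios |>
    mutate(
      in_hospital_bites = inhospital_prevalence(.data$hospital_deaths,
                                                .data$cfr),
      total_bites = .data$in_hospital_bites * (1 + .data$out_to_in_ratio),
      envenomations = .data$total_bites * .data$envenomation_share,
      dry_bites = .data$total_bites * (1 - .data$envenomation_share))
  attr(out, "range") <- c(min = min(out$total_bites),
                          max = max(out$total_bites))
  out
}

#' Split total bites into envenomations and dry bites
#'
#' @param total Total bites.
#' @param envenomation_share Share of bites with systemic envenomation
#'   (default 0.70, the share observed across hospital studies).
#' @return Tibble `total`, `envenomations`, `dry_bites`; the two parts sum
#'   to the total exactly (rounding is left to report formatting).
#' @export
#' @examples
#' partition_envenomation(1.77e6)
partition_envenomation <- function(total, envenomation_share = 0.70) {
  if (any(envenomation_share < 0 | envenomation_share > 1)) {
    abort("`envenomation_share` must be in [0, 1].",
          class = "snakeburden_validation_error")
  }
  tibble(total = total,
         envenomations = total * envenomation_share,
         dry_bites = total * (1 - envenomation_share))
}

#' Illustrative prevalence scenarios
#'
#' A bracketing pair of assumptions for 2015: about 14,300 in-hospital
#' deaths (annual national deaths times a 23% in-hospital share), a 3.2%
#' in-hospital case-fatality rate, out-of-hospital to in-hospital bite
#' ratios of 1.48 and 2.96 (roughly 20-40 bites per death), and a 70%
#' envenomation share. These are illustrative defaults; the scenario grid is
#' an explicit user input.
#'
#' @param year Scenario year (default 2015).
#' @return A scenarios tibble for [total_bites()].
#' @export
default_prevalence_scenarios <- function(year = 2015) {
  tibble(
    scenario = c("conservative", "high"),
    year = year,
    hospital_deaths = 14300,
    cfr = 0.032,
    out_to_in_ratio = c(1.48, 2.96),
    envenomation_share = 0.70)
}
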