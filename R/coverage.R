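# Surveillance coverage: officially reported hospital deaths versus
# model-estimated in-hospital deaths.

#' Surveillance coverage table
#'
#' Joins officially reported snakebite deaths to model-estimated totals per
#' region, computes estimated in-hospital deaths
#' (`est_total_deaths * in_hospital_fraction`) and the coverage percentage
#' (`reported_deaths / est_hospital_deaths * 100`), and appends a national
#' aggregate computed from summed numerators and denominators (never from
#' averaged percentages).
#'
#' @param reported Tibble `region`, `reported_bites`, `reported_deaths`
#'   (counts, typically thousands).
#' @param estimated Tibble `region`, `est_total_deaths`,
#'   `in_hospital_fraction`.
#' @param mode `"raw"` keeps full precision; `"table"` applies report
#'   rounding (one decimal for counts in thousands, integer percent).
#' @param aggregate_name Name of the appended aggregate row.
#' @return Tibble with one row per region plus the aggregate row (flagged by
#'   `is_aggregate`): `region`, `reported_bites`, `reported_deaths`,
#'   `est_total_deaths`, `in_hospital_fraction`, `est_hospital_deaths`,
#'   `coverage_pct`.
#' @export
coverage_table <- function(reported, estimated, mode = c("raw", "table"),
                           aggregate_name = "India") {
  mode <- match.arg(mode)
  stopifnot_cols(reported, c("region", "reported_bites", "reported_deaths"),
                 "reported")
  stopifnot_cols(estimated,
                 c("region", "est_total_deaths", "in_hospital_fraction"),
                 "estimated")
  only_rep <- setdiff(reported$region, estimated$region)
  only_est <- setdiff(estimated$region, reported$region)
  if (length(only_rep) > 0 || length(only_est) > 0) {
    abort(sprintf(
      "Regions do not reconcile. Only in reported: %s. Only in estimated: %s.",
      paste(only_rep, collapse = ", "), paste(only_est, collapse = ", ")),
      class = "snakeburden_reconciliation_error")
  }
  rows <- reported |>
    left_join(estimated, by = "region") |>
    mutate(
      est_hospital_deaths = .data$est_total_deaths *
        .data$in_hospital_fraction,
      coverage_pct = ifelse(.data$est_hospital_deaths > 0,
                            .data$reported_deaths /
                              .data$est_hospital_deaths * 100, NA_real_),
      is_aggregate = FALSE)
  agg <- rows |>
    summarise(
      region = aggregate_name,
      reported_bites = sum(.data$reported_bites),
      reported_deaths = sum(.data$reported_deaths),
      est_total_deaths = sum(.data$est_total_deaths),
      est_hospital_deaths = sum(.data$est_hospital_deaths)) |>
    mutate(
      in_hospital_fraction = .data$est_hospital_deaths /
        .data$est_total_deaths,
      coverage_pct = .data$reported_deaths / .data$est_hospital_deaths * 100,
      is_aggregate = TRUE)
  out <- bind_rows(rows, agg) |>
    select("region", "reported_bites", "reported_deaths",
           "est_total_deaths", "in_hospital_fraction",
           "est_hospital_deaths", "coverage_pct", "is_aggregate")
  if (mode == "table") {
    out <- mutate(out,
                  across(c("reported_bites", "reported_deaths",
                           "est_total_deaths", "est_hospital_deaths"),
                         ~ round(.x, 1)),
                  coverage_pct = round(.data$coverage_pct))
  }
  out
}
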