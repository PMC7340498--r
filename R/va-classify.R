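# Dual-coder inclusion/exclusion rules for snakebite deaths and the
# lower/central/upper plausible-range construction built on them.

snakebite_codes <- function() c("X20", "X27", "X29")

icd10_ok <- function(code) grepl("^[A-Z][0-9]{2}[0-9]?$", code)

#' Classify death records by the dual-coder snakebite rule
#'
#' Applies the inclusion rules used with dual physician-coded verbal
#' autopsies: a record is `included_agreed` when both coders assigned X20
#' (venomous snake); it is a review *candidate* when at least one coder
#' assigned one of X20/X27/X29 but the codes do not dual-agree on X20; all
#' other records are `excluded`. Candidates are resolved by an explicit
#' review table (`record_id`, `is_snakebite`); a candidate absent from the
#' review table, or reviewed negative, is excluded.
#'
#' @param records Tibble of death records with `record_id`, `coder1_icd10`,
#'   `coder2_icd10`.
#' @param review Optional tibble `record_id`, `is_snakebite` (logical) with
#'   the adjudicated result for review candidates. In synthetic pipelines
#'   this is typically built from the generator's `cause_true` column.
#' @return `records` with added columns `classification` (one of
#'   `included_agreed`, `included_after_review`, `excluded_candidate`,
#'   `excluded`), `is_candidate`, `any_x20` and `is_snakebite` (final
#'   inclusion flag).
#' @export
#' @examples
#' recs <- tibble::tibble(record_id = c("a", "b", "c"),
#'                        coder1_icd10 = c("X20", "X20", "J18"),
#'                        coder2_icd10 = c("X20", "X27", "I21"))
#' classify_records(recs)$classification
classify_records <- function(records, review = NULL) {
  stopifnot_cols(records, c("record_id", "coder1_icd10", "coder2_icd10"),
                 "records")
  bad <- !icd10_ok(records$coder1_icd10) | !icd10_ok(records$coder2_icd10)
  if (any(bad)) {
    abort(sprintf("Malformed ICD-10 code(s) in record(s): %s",
                  paste(head(records$record_id[bad], 5), collapse = ", ")),
          class = "snakeburden_validation_error")
  }
  snake <- snakebite_codes()
  c1 <- records$coder1_icd10
  c2 <- records$coder2_icd10
  agreed <- c1 == "X20" & c2 == "X20"
  candidate <- !agreed & (c1 %in% snake | c2 %in% snake)

  reviewed_yes <- rep(FALSE, nrow(records))
  reviewed_any <- rep(FALSE, nrow(records))
  if (!is.null(review)) {
    stopifnot_cols(review, c("record_id", "is_snakebite"), "review")
    m <- match(records$record_id, review$record_id)
    reviewed_any <- !is.na(m)
    reviewed_yes <- reviewed_any & review$is_snakebite[m] %in% TRUE
  }

  records |>
    mutate(
      any_x20 = c1 == "X20" | c2 == "X20",
      is_candidate = candidate,
      reviewed = reviewed_any & candidate,
      classification = case_when(
        agreed ~ "included_agreed",
        candidate & reviewed_yes ~ "included_after_review",
        candidate ~ "excluded_candidate",
        TRUE ~ "excluded"),
      is_snakebite = .data$classification %in%
        c("included_agreed", "included_after_review"))
}

#' Lower/central/upper snakebite death counts from coder agreement
#'
#' Builds the plausible-range counts: the lower bound counts records on which
#' both physicians immediately agreed (X20/X20); the central count adds
#' review-confirmed candidates; the upper bound counts every record where at
#' least one coder assigned X20 (plus review-confirmed X27/X29-only
#' candidates, so the upper bound always contains the central count). With
#' `include_x29_only = TRUE` every X27/X29-only candidate counts toward the
#' upper bound regardless of review (the rule is ambiguous between "either
#' physician coding snakebite" and "X20 or X29", so both readings are
#' supported). The immediate-agreement fraction is
#' `lower / (lower + number of candidates)`.
#'
#' @param classified Output of [classify_records()].
#' @param include_x29_only Should all X27/X29-only candidates count toward
#'   the upper bound (not just review-confirmed ones)? Default `FALSE`.
#' @return One-row tibble: `lower`, `central`, `upper`,
#'   `immediate_agreement_fraction` (NA on empty input).
#' @export
coding_bounds <- function(classified, include_x29_only = FALSE) {
  stopifnot_cols(classified, c("classification", "is_candidate", "any_x20"),
                 "classified")
  lower <- sum(classified$classification == "included_agreed")
  central <- lower +
    sum(classified$classification == "included_after_review")
  n_cand <- sum(classified$is_candidate)
  x29_only <- classified$is_candidate & !classified$any_x20
  upper <- lower + sum(classified$is_candidate & classified$any_x20) +
    if (include_x29_only) sum(x29_only)
    else sum(x29_only &
               classified$classification == "included_after_review")
  tibble(
    lower = lower, central = central, upper = upper,
    immediate_agreement_fraction =
      if (lower + n_cand > 0) lower / (lower + n_cand) else NA_real_)
}

#' Build a review table from the generator's true causes
#'
#' Convenience for synthetic pipelines: candidates are adjudicated using the
#' simulated true cause, mirroring how physician review resolved
#' disagreements.
#'
#' @param records Death records carrying a `cause_true` column.
#' @return Tibble `record_id`, `is_snakebite`.
#' @export
review_from_truth <- function(records) {
  stopifnot_cols(records, c("record_id", "cause_true"), "records")
  tibble(record_id = records$record_id,
         is_snakebite = records$cause_true == "snakebite")
}
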