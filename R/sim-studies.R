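#' Simulate literature bite/death study tables
#'
#' Emulates a systematic-review table of snakebite studies: heavy-tailed
#' study sizes (log-normal bite counts), deaths drawn from an overdispersed
#' binomial (beta-binomial; `dispersion = 0` collapses to binomial with
#' success probability exactly `true_cfr`), a configurable fraction of
#' outlier studies with inflated case fatality, and a small number of
#' autopsy-type studies that report deaths only.
#'
#' @param n_studies Number of studies (>= 3).
#' @param true_cfr True in-hospital case-fatality rate in (0, 1), or 0 for a
#'   degenerate no-deaths table.
#' @param dispersion Beta-binomial overdispersion (0 = plain binomial).
#' @param seed Integer seed.
#' @param outlier_fraction Fraction of non-autopsy studies whose case
#'   fatality is replaced by `outlier_cfr`.
#' @param outlier_cfr Case-fatality rate of planted outlier studies.
#' @param autopsy_fraction Fraction of studies that are autopsy series
#'   (deaths only, bites missing).
#' @return Tibble `study_id`, `study_type`, `bites`, `deaths`.
#' @export
#' @examples
#' generate_literature_studies(10, true_cfr = 0.032, seed = 1)
generate_literature_studies <- function(n_studies, true_cfr,
                                        dispersion = 0, seed = 1L,
                                        outlier_fraction = 0,
                                        outlier_cfr = 0.5,
                                        autopsy_fraction = 0.09) {
  if (n_studies < 3) {
    abort("At least 3 studies are required.",
          class = "snakeburden_insufficient_data")
  }
  if (true_cfr < 0 || true_cfr >= 1) {
    abort("`true_cfr` must be in [0, 1).",
          class = "snakeburden_config_error")
  }
  set.seed(seed)
  n <- as.integer(n_studies)
  n_aut <- round(autopsy_fraction * n)
  type <- c(rep("autopsy", n_aut),
            sample(c("hospital", "community", "EMS"), n - n_aut,
                   replace = TRUE, prob = c(0.92, 0.06, 0.02)))
  bites <- pmax(20L, round(rlnorm(n, meanlog = log(400), sdlog = 1.1)))
  p <- if (dispersion > 0 && true_cfr > 0) {
    phi <- 1 / dispersion
    rbeta(n, true_cfr * phi, (1 - true_cfr) * phi)
  } else {
    rep(true_cfr, n)
  }
  n_out <- round(outlier_fraction * (n - n_aut))
  if (n_out > 0) {
    idx <- which(type != "autopsy")[seq_len(n_out)]
    p[idx] <- outlier_cfr
  }
  deaths <- rbinom(n, bites, p)
  tibble(
    study_id = sprintf("S%03d", seq_len(n)),
    study_type = type,
    bites = ifelse(type == "autopsy", NA_integer_, bites),
    deaths = ifelse(type == "autopsy", rpois(n, 30), deaths))
}
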