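#' Estimate adult GP-registered populations from practice registers
#'
#' Reproduces the construction of small-area adult population estimates
#' from quarterly practice-level releases: the official data give, per
#' quarter, the number of residents of each area registered at each
#' practice (all ages) and the proportion of each practice's whole register
#' aged 25 or over, but no small-area age breakdown. The adult count for an
#' area-quarter is therefore estimated by multiplying each practice's
#' area count by that practice's adult fraction and summing over practices;
#' the annual estimate is the unweighted mean over the quarterly releases
#' available for that year.
#'
#' @param registers A register collection: a list with element `register`,
#'   a tibble with columns `practice_id`, `area_id`, `year`, `quarter`,
#'   `count`, `frac_25plus`. Missing practice-quarters are simply absent
#'   rows; each is excluded from that quarter's sum with a message.
#' @param area_ids Areas to report (rows with other areas are ignored);
#'   defaults to all areas present.
#' @return Tibble `area_id`, `year`, `estimate` (persons aged 25+),
#'   ordered by year then area.
#' @examples
#' reg <- list(register = tibble::tibble(
#'   practice_id = c("P1", "P2"), area_id = "A", year = 2014, quarter = 1,
#'   count = c(100, 50), frac_25plus = c(0.8, 0.6)))
#' nhs_population_estimate(reg)  # 100*0.8 + 50*0.6 = 110
#' @export
nhs_population_estimate <- function(registers, area_ids = NULL) {
  reg <- registers$register
  stopifnot(all(c("practice_id", "area_id", "year", "quarter", "count",
                  "frac_25plus") %in% names(reg)))
  if (is.null(area_ids)) area_ids <- sort(unique(reg$area_id))
  reg <- dplyr::filter(reg, .data$area_id %in% area_ids)

  # a practice missing from a quarterly release contributes nothing to that
  # quarter; report it so the exclusion is visible
  releases <- dplyr::distinct(reg, .data$year, .data$quarter)
  per_practice <- dplyr::distinct(reg, .data$practice_id, .data$year,
                                  .data$quarter)
  expected <- tidyr::expand_grid(
    practice_id = unique(reg$practice_id), releases)
  gaps <- dplyr::anti_join(expected, per_practice,
                           by = c("practice_id", "year", "quarter"))
  if (nrow(gaps) > 0) {
    message(sprintf(
      "nhs_population_estimate: %d practice-quarter(s) missing from releases; excluded",
      nrow(gaps)))
  }

  reg |>
    dplyr::mutate(adults = .data$count * .data$frac_25plus) |>
    dplyr::group_by(.data$area_id, .data$year, .data$quarter) |>
    dplyr::summarise(q_est = sum(.data$adults), .groups = "drop") |>
    dplyr::group_by(.data$area_id, .data$year) |>
    dplyr::summarise(estimate = mean(.data$q_est), .groups = "drop") |>
    dplyr::arrange(.data$year, .data$area_id)
}
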