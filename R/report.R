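#' Relative-risk summary of the referral model
#'
#' Exponentiates each coefficient's draws and reports the posterior median
#' and equal-tailed credible interval on the rate-ratio (RR) scale, rounded
#' to three decimal places. A coefficient is flagged significant when its
#' interval (computed before rounding) excludes the null RR of 1.
#'
#' @param fit A [`referral_glmm_fit`][fit_referral_glmm].
#' @param level Credible level (default 0.95).
#' @return Tibble of class `rr_summary`: `parameter`, `rr`, `lower`,
#'   `upper`, `significant`.
#' @export
rr_summary <- function(fit, level = 0.95) {
  g <- fit$draws$gamma
  if (is.null(g) || nrow(g) < 100) {
    stop("summary error: need at least 100 retained draws", call. = FALSE)
  }
  a <- (1 - level) / 2
  out <- purrr::map_dfr(colnames(g), function(nm) {
    rr <- exp(g[, nm])
    q <- stats::quantile(rr, c(0.5, a, 1 - a), names = FALSE)
    tibble::tibble(parameter = nm,
                   rr = round(q[1], 3), lower = round(q[2], 3),
                   upper = round(q[3], 3),
                   significant = q[2] > 1 | q[3] < 1)
  })
  class(out) <- c("rr_summary", class(out))
  out
}

#' Percent change implied by a rate ratio
#'
#' `(rr - 1) * 100`, to one decimal place: the narrative form of a
#' coefficient ("a 1% covariate increase is associated with an x% change in
#' referral rate").
#'
#' @param rr Positive rate ratio(s).
#' @return Numeric vector of signed percent changes.
#' @examples
#' percent_change(1.017)  # +1.7
#' @export
percent_change <- function(rr) {
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop("rate ratios must be positive", call. = FALSE)
  }
  round((rr - 1) * 100, 1)
}

#' Full-intervention effect for a given year
#'
#' Percent change in referral rate for an area at `coverage_delta` percent
#' intervention coverage relative to none, in a given study year. Per
#' retained draw the combined per-percentage-point coefficient (coverage
#' main effect plus that year's interaction; main effect only in the
#' baseline year) is multiplied by the coverage difference and
#' exponentiated; the posterior median and equal-tailed interval of
#' `(exp(combined * delta) - 1) * 100` are reported. Summarising per draw
#' rather than powering the rounded median RR is what makes the result
#' differ slightly from `(RR^delta - 1) * 100` computed from a printed
#' table.
#'
#' @param fit A [`referral_glmm_fit`][fit_referral_glmm].
#' @param year Study year of interest.
#' @param coverage_delta Coverage difference in percentage points,
#'   `(0, 100]`; 100 is full intervention.
#' @param level Credible level.
#' @return One-row tibble `year`, `coverage_delta`, `pct_change`, `lower`,
#'   `upper` (percent scale, 1 dp).
#' @export
full_intervention_effect <- function(fit, year, coverage_delta = 100,
                                     level = 0.95) {
  stopifnot(coverage_delta > 0, coverage_delta <= 100)
  g <- fit$draws$gamma
  yrs <- fit$design$years
  if (!year %in% yrs) stop("unknown study year: ", year, call. = FALSE)
  comb <- g[, "mbrn"]
  if (year != fit$design$baseline_year) {
    inter <- paste0("year", year, ":mbrn")
    comb <- comb + g[, inter]
  }
  pct <- (exp(comb * coverage_delta) - 1) * 100
  a <- (1 - level) / 2
  q <- stats::quantile(pct, c(0.5, a, 1 - a), names = FALSE)
  tibble::tibble(year = year, coverage_delta = coverage_delta,
                 pct_change = round(q[1], 1), lower = round(q[2], 1),
                 upper = round(q[3], 1))
}

#' Predicted referral rates under intervention and no intervention
#'
#' The interaction-plot computation: for each study year and each coverage
#' level, the predicted number of referrals per 100 CRD patients with every
#' other covariate fixed at its median over the whole data set and the
#' random intercept at its prior mean of zero. Per draw the linear
#' predictor at the median design point is exponentiated and scaled to 100
#' patients; posterior medians and equal-tailed intervals are returned.
#'
#' @param fit A [`referral_glmm_fit`][fit_referral_glmm].
#' @param coverage_levels Coverage percents to contrast (default 0 and 100).
#' @param level Credible level.
#' @return Tibble of class `interaction_predictions`: `year`, `coverage`,
#'   `rate` (per 100 CRD patients), `lower`, `upper`.
#' @export
interaction_predictions <- function(fit, coverage_levels = c(0, 100),
                                    level = 0.95) {
  g <- fit$draws$gamma
  dat <- fit$design$data
  med <- vapply(c("age65_74", "age75plus", "male", "distance_km", "imd"),
                function(v) stats::median(dat[[v]]), numeric(1))
  if (anyNA(med)) stop("missing median covariates", call. = FALSE)
  yrs <- fit$design$years
  a <- (1 - level) / 2
  out <- tidyr::expand_grid(year = yrs, coverage = coverage_levels)
  res <- purrr::pmap_dfr(out, function(year, coverage) {
    d <- stats::setNames(numeric(ncol(g)), colnames(g))
    d["intercept"] <- 1
    d[names(med)] <- med
    if (year != fit$design$baseline_year) {
      d[paste0("year", year)] <- 1
      d[paste0("year", year, ":mbrn")] <- coverage
    }
    d["mbrn"] <- coverage
    rate <- 100 * exp(drop(g %*% d))
    q <- stats::quantile(rate, c(0.5, a, 1 - a), names = FALSE)
    tibble::tibble(year = year, coverage = coverage,
                   rate = q[1], lower = q[2], upper = q[3])
  })
  class(res) <- c("interaction_predictions", class(res))
  res
}

#' Annual referral totals and per-area averages
#'
#' Study-year totals of referral counts and the average per area, rounded
#' to two decimal places.
#'
#' @param referrals Tibble with columns `year` and `y` (one row per
#'   area-year), or with columns `year` and `total` (pre-aggregated).
#' @param n_areas Number of areas; inferred from `area_id` when present.
#' @return Tibble `year`, `total`, `avg_per_area`.
#' @examples
#' summarize_annual(tibble::tibble(year = 2012, total = 968), n_areas = 204)
#' @export
summarize_annual <- function(referrals, n_areas = NULL) {
  if ("total" %in% names(referrals)) {
    tot <- dplyr::distinct(referrals, .data$year, .data$total)
  } else {
    tot <- referrals |>
      dplyr::group_by(.data$year) |>
      dplyr::summarise(total = sum(.data$y), .groups = "drop")
    if (is.null(n_areas) && "area_id" %in% names(referrals)) {
      n_areas <- dplyr::n_distinct(referrals$area_id)
    }
  }
  if (is.null(n_areas) || n_areas <= 0) {
    stop("n_areas must be a positive count", call. = FALSE)
  }
  dplyr::arrange(tot, .data$year) |>
    dplyr::mutate(avg_per_area = round(.data$total / n_areas, 2))
}

#' Percent error of register counts against official estimates
#'
#' Per-cell percentage difference `(cdw - nhs) / nhs * 100` over the years
#' where official estimates exist, plus per-year medians — the boxplot
#' summary showing register error growing back in time.
#'
#' @param panel Population panel tibble.
#' @return Tibble of class `cdw_error_summary`: `area_id`, `year`,
#'   `pct_diff`.
#' @export
cdw_error_summary <- function(panel) {
  out <- panel |>
    dplyr::filter(!is.na(.data$p_nhs)) |>
    dplyr::mutate(pct_diff = (.data$p_cdw - .data$p_nhs) /
                    .data$p_nhs * 100) |>
    dplyr::select("area_id", "year", "pct_diff")
  class(out) <- c("cdw_error_summary", class(out))
  out
}
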