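#' Tidy posterior summaries of fitted objects
#'
#' `tidy()` returns one row per model parameter with the posterior median
#' and equal-tailed 95% interval; `glance()` returns a one-row summary of
#' the fit. For the referral model, `tidy()` works on the log scale (use
#' [rr_summary()] for the rate-ratio table).
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

post_sum <- function(draws, name) {
  q <- stats::quantile(draws, c(0.5, 0.025, 0.975), names = FALSE)
  tibble::tibble(term = name, estimate = q[1], conf.low = q[2],
                 conf.high = q[3])
}

#' @rdname tidiers
#' @export
tidy.stcar_fit <- function(x, ...) {
  d <- x$draws
  dplyr::bind_rows(
    purrr::map_dfr(colnames(d$beta),
                   function(nm) post_sum(d$beta[, nm],
                                         paste0("beta_", nm))),
    post_sum(d$sigma2, "sigma2"), post_sum(d$tau2, "tau2"),
    post_sum(d$rho_s, "rho_s"), post_sum(d$rho_t, "rho_t"))
}

#' @rdname tidiers
#' @export
glance.stcar_fit <- function(x, ...) {
  tibble::tibble(n_areas = length(x$area_ids), n_years = length(x$years),
                 n_draws = length(x$draws$sigma2),
                 n_imputed_cells = nrow(x$missing),
                 accept_rho_s = unname(x$acceptance["rho_s"]),
                 accept_rho_t = unname(x$acceptance["rho_t"]))
}

#' @rdname tidiers
#' @export
tidy.referral_glmm_fit <- function(x, ...) {
  d <- x$draws
  dplyr::bind_rows(
    purrr::map_dfr(colnames(d$gamma),
                   function(nm) post_sum(d$gamma[, nm], nm)),
    post_sum(d$kappa2, "kappa2"))
}

#' @rdname tidiers
#' @export
glance.referral_glmm_fit <- function(x, ...) {
  k <- stats::quantile(x$draws$kappa2, c(0.5, 0.025, 0.975), names = FALSE)
  tibble::tibble(n_areas = length(x$area_ids),
                 n_cells = nrow(x$design$X),
                 n_draws = length(x$draws$kappa2),
                 kappa2 = k[1], kappa2_low = k[2], kappa2_high = k[3],
                 accept_gamma = unname(x$acceptance["gamma"]),
                 accept_z = unname(x$acceptance["z"]),
                 offset_resampled = x$resample_offset)
}
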