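#' Moran's I with a permutation test
#'
#' Global spatial autocorrelation of a vector of area-level values on a
#' lattice, using the binary (non-row-standardised) neighbourhood matrix and
#' the classical normalising constant:
#' \deqn{I = \frac{N}{\sum_{ij} w_{ij}}
#'   \frac{\sum_{ij} w_{ij} (v_i - \bar v)(v_j - \bar v)}
#'        {\sum_i (v_i - \bar v)^2}.}
#' Significance is assessed by random permutation of the values over areas;
#' the two-sided p-value is `(1 + #permuted |I*| >= |I|) / (n_perm + 1)`.
#' Under spatial independence `E[I] = -1/(N-1)`.
#'
#' @param values Numeric vector, one value per lattice area, in lattice
#'   order. Must not be constant.
#' @param lattice An [`area_lattice`][build_grid_lattice].
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional integer seed making the permutation draw
#'   reproducible without touching the caller's RNG state.
#' @return A one-row tibble with columns `statistic`, `expectation`
#'   (`-1/(N-1)`), `p_value`, and `n_perm`.
#' @examples
#' lat <- build_grid_lattice(5, 5)
#' morans_i(rnorm(25), lat, n_perm = 199, seed = 1)
#' @export
morans_i <- function(values, lattice, n_perm = 9999, seed = NULL) {
  W <- lattice$W
  N <- nrow(W)
  stopifnot(length(values) == N, n_perm >= 1)
  v <- values - mean(values)
  ss <- sum(v^2)
  if (ss == 0) {
    stop("degenerate input: values are constant (zero variance)",
         call. = FALSE)
  }
  s0 <- sum(W)
  istat <- function(z) (N / s0) * drop(crossprod(z, W %*% z)) / sum(z^2)
  I_obs <- istat(v)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(k) istat(sample(v)), numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(I_obs))) / (n_perm + 1)
  tibble::tibble(statistic = I_obs, expectation = -1 / (N - 1),
                 p_value = p, n_perm = n_perm)
}

#' Lag-1 temporal autocorrelation per area
#'
#' The plug-in sample autocorrelation at lag 1 for each area's time series
#' \eqn{z_1, \ldots, z_T}:
#' \deqn{r_1 = \frac{\sum_{t=1}^{T-1} (z_t - \bar z)(z_{t+1} - \bar z)}
#'                  {\sum_{t=1}^{T} (z_t - \bar z)^2},}
#' i.e. the estimator used by [stats::acf()], whose denominator is the full
#' series sum of squares about the series mean. (The alternative that
#' divides by `T - 1` covariance pairs only is not used; the plug-in form is
#' kept fixed throughout.) Constant series have an undefined autocorrelation
#' and are dropped from the mean with a warning.
#'
#' @param series_by_area Numeric matrix, areas in rows and time points in
#'   columns (`N x T`, `T >= 3`), or a data frame in long format with
#'   columns `area_id`, `year` and a single value column.
#' @param value Column holding the series values when `series_by_area` is a
#'   long data frame. Defaults to `"value"`.
#' @return A list with `per_area` (tibble `area_id`, `acf1`) and `mean`
#'   (unweighted average of the defined per-area values).
#' @export
lag1_autocorrelation <- function(series_by_area, value = "value") {
  if (is.data.frame(series_by_area)) {
    wide <- tidyr::pivot_wider(
      series_by_area[, c("area_id", "year", value)],
      names_from = "year", values_from = dplyr::all_of(value))
    m <- as.matrix(wide[, -1])
    rownames(m) <- wide$area_id
    series_by_area <- m
  }
  m <- series_by_area
  stopifnot(is.matrix(m), ncol(m) >= 3)
  ids <- rownames(m)
  if (is.null(ids)) ids <- sprintf("A%03d", seq_len(nrow(m)))
  Tn <- ncol(m)
  ctr <- m - rowMeans(m)
  num <- rowSums(ctr[, -Tn, drop = FALSE] * ctr[, -1, drop = FALSE])
  den <- rowSums(ctr^2)
  acf1 <- ifelse(den > 0, num / den, NA_real_)
  if (anyNA(acf1)) {
    warning(sprintf(
      "%d constant series excluded from the lag-1 autocorrelation mean (%s)",
      sum(is.na(acf1)), paste(ids[is.na(acf1)], collapse = ", ")),
      call. = FALSE)
  }
  list(per_area = tibble::tibble(area_id = ids, acf1 = acf1),
       mean = mean(acf1, na.rm = TRUE))
}

#' Spatio-temporal residual diagnostics for the population GLM
#'
#' Fits the naive ordinary-least-squares regression of `log(p_nhs)` on the
#' stage-one covariates over the observed cells (i.e. the model without any
#' structured random effect) and summarises the spatio-temporal correlation
#' left in its residuals: Moran's I with a permutation p-value for each
#' year separately, and the per-area lag-1 temporal autocorrelation with its
#' mean across areas. Strong positive values on both axes are the usual
#' justification for moving to the spatio-temporal CAR model fitted by
#' [fit_stcar()].
#'
#' @param panel A population panel tibble with columns `area_id`, `year`,
#'   `p_cdw`, `p_nhs` (NA where unpublished), `nonsharing_prop`.
#' @param lattice The matching `area_lattice`.
#' @param n_perm,seed Passed to [morans_i()].
#' @return A list of class `stcar_diagnostics` with `moran` (tibble: `year`,
#'   `statistic`, `expectation`, `p_value`), `lag1` (per-area tibble) and
#'   `lag1_mean`. Years with fewer than the full set of areas observed are
#'   skipped.
#' @export
glm_residual_diagnostics <- function(panel, lattice, n_perm = 9999,
                                     seed = NULL) {
  obs <- dplyr::filter(panel, !is.na(.data$p_nhs))
  if (length(unique(obs$year)) < 3) {
    stop("need p_nhs observed for at least 3 years", call. = FALSE)
  }
  X <- stage1_design(obs)
  y <- log(obs$p_nhs)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    stop("diagnostics error: singular stage-one design", call. = FALSE)
  }
  res <- obs
  res$resid <- fit$residuals

  years <- sort(unique(res$year))
  moran <- purrr::map_dfr(seq_along(years), function(k) {
    yr <- years[k]
    r <- dplyr::filter(res, .data$year == yr)
    r <- r[match(lattice$area_ids, r$area_id), ]
    mi <- morans_i(r$resid, lattice, n_perm = n_perm,
                   seed = if (is.null(seed)) NULL else seed + k)
    dplyr::bind_cols(tibble::tibble(year = yr), mi)
  })

  lag1 <- lag1_autocorrelation(res[, c("area_id", "year", "resid")],
                               value = "resid")
  structure(list(moran = moran, lag1 = lag1$per_area,
                 lag1_mean = lag1$mean),
            class = "stcar_diagnostics")
}

#' @export
print.stcar_diagnostics <- function(x, ...) {
  cat("Residual spatio-temporal diagnostics (OLS on log official counts)\n")
  cat(sprintf("  Moran's I by year: %s\n",
              paste(sprintf("%.3f", x$moran$statistic), collapse = ", ")))
  cat(sprintf("  permutation p-values: %s\n",
              paste(format.pval(x$moran$p_value), collapse = ", ")))
  cat(sprintf("  mean lag-1 temporal autocorrelation: %.4f\n", x$lag1_mean))
  invisible(x)
}

# Stage-one fixed-effects design: intercept, log CDW count, linear time
# index over the panel's years, proportion at non-sharing practices.
stage1_design <- function(panel) {
  yrs <- sort(unique(panel$year))
  cbind(intercept = 1,
        log_p_cdw = log(panel$p_cdw),
        time = match(panel$year, yrs),
        nonsharing = panel$nonsharing_prop)
}

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
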