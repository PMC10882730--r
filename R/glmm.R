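#' Build the stage-two regression design
#'
#' Constructs the fixed-effect design of the referral model: intercept, two
#' age-proportion terms and proportion male (percent of the adult
#' population), road distance to the nearest hospital (km), deprivation
#' score, study-year indicators (the baseline year carries none), the
#' intervention coverage percent (`mbrn_pct`, 0--100, computed for all study
#' years including pre-intervention ones), and the year-by-coverage
#' interaction products. With eight study years that is 21 columns, in the
#' fixed order: `intercept`, `age65_74`, `age75plus`, `male`,
#' `distance_km`, `imd`, `year<y>` for each non-baseline year, `mbrn`,
#' `year<y>:mbrn` for each non-baseline year. Percent covariates enter on
#' the 0--100 scale, so each coefficient is a per-percentage-point log
#' rate ratio.
#'
#' @param covariates Tibble with columns `area_id`, `year`, `age65_74`,
#'   `age75plus`, `male`, `distance_km`, `imd`, `mbrn_pct`.
#' @param baseline_year Reference level of the year factor; defaults to the
#'   earliest year present and must be one of the years.
#' @return List with `X` (numeric matrix, rows in year-major area order),
#'   `data` (the covariates reordered to match), `years`, `baseline_year`.
#' @export
build_design <- function(covariates, baseline_year = NULL) {
  years <- sort(unique(covariates$year))
  if (is.null(baseline_year)) baseline_year <- years[1]
  if (!baseline_year %in% years) {
    stop("design error: baseline year ", baseline_year,
         " not present in the data", call. = FALSE)
  }
  dat <- dplyr::arrange(covariates, .data$year, .data$area_id)
  other <- setdiff(years, baseline_year)
  yr_ind <- vapply(other, function(yy) as.numeric(dat$year == yy),
                   numeric(nrow(dat)))
  colnames(yr_ind) <- paste0("year", other)
  inter <- yr_ind * dat$mbrn_pct
  colnames(inter) <- paste0("year", other, ":mbrn")
  X <- cbind(intercept = 1,
             age65_74 = dat$age65_74, age75plus = dat$age75plus,
             male = dat$male, distance_km = dat$distance_km, imd = dat$imd,
             yr_ind, mbrn = dat$mbrn_pct, inter)
  list(X = X, data = dat, years = years, baseline_year = baseline_year)
}

#' Dichotomise intervention coverage
#'
#' Classifies an area as an intervention ("MBRN") area if strictly more
#' than 50% of its GP-registered population is registered at a practice
#' that joined the network; used for exploratory summaries only — the model
#' itself uses the continuous coverage percent.
#'
#' @param coverage_percent Numeric vector in `[0, 100]`.
#' @return Factor with levels `non-MBRN`, `MBRN`.
#' @examples
#' classify_mbrn(c(0, 50, 50.1))  # non-MBRN, non-MBRN, MBRN
#' @export
classify_mbrn <- function(coverage_percent) {
  if (any(is.na(coverage_percent)) ||
      any(coverage_percent < 0 | coverage_percent > 100)) {
    stop("coverage percent must lie in [0, 100]", call. = FALSE)
  }
  factor(ifelse(coverage_percent > 50, "MBRN", "non-MBRN"),
         levels = c("non-MBRN", "MBRN"))
}

#' Fit the Poisson referral model with offset uncertainty propagation
#'
#' Fits, by Metropolis-within-Gibbs, the random-intercept Poisson model
#' \deqn{Y_{it} \sim \mathrm{Poisson}(\hat R_{it}
#'   \exp(d_{it}^\top \gamma + Z_i)), \quad Z_i \sim N(0, \kappa^2),}
#' where the offset \eqn{\hat R_{it}} is the adjusted CRD patient count
#' from stage one. To propagate stage-one uncertainty, one stage-one draw
#' index is selected uniformly at random at *every* iteration and the
#' offset recomputed for cells whose denominator was imputed, before the
#' Poisson likelihood is evaluated. The offset-index stream uses its own
#' RNG seed, so changing it leaves the parameter proposal stream untouched
#' (with degenerate identical offset draws, runs with different
#' `offset_seed` give identical chains).
#'
#' Updates: blocked random-walk Metropolis for `gamma` with proposal
#' covariance from the maximum-likelihood Poisson fit and a global scale
#' adapted during burn-in; simultaneous univariate random-walk Metropolis
#' for each `Z_i` (conditionally independent given `gamma`, `kappa2`);
#' conjugate inverse-gamma Gibbs for `kappa2`. Priors: `gamma ~ N(0, 1e5)`
#' elementwise, `kappa2 ~ Inverse-Gamma(1, 0.01)`.
#'
#' @param referrals Tibble with `area_id`, `year`, `y` and the covariate
#'   columns required by [build_design()].
#' @param offset An [`adjusted_denominator`][adjust_denominator], or a
#'   numeric vector of fixed positive offsets aligned to the year-major
#'   ordering of the referral cells.
#' @param mcmc An [mcmc_config()].
#' @param baseline_year Passed to [build_design()].
#' @param resample_offset If `FALSE`, the offset is fixed at its per-cell
#'   posterior median instead of being resampled (used to quantify how much
#'   denominator uncertainty widens the intervals).
#' @param offset_seed Seed of the offset-index stream; defaults to
#'   `mcmc$seed + 1`.
#' @param fix Optional named list pinning `kappa2` and/or `z` (numeric,
#'   one per area) for oracle tests; their updates are skipped.
#' @return Object of class `referral_glmm_fit`: `draws` (`gamma`, `kappa2`,
#'   `z`, `offset_index`), `design` (from [build_design()]), `area_ids`,
#'   `acceptance` (post-burn-in rates for the `gamma` block and mean over
#'   `z`), `config`.
#' @export
fit_referral_glmm <- function(referrals, offset, mcmc = mcmc_config(30000,
                                                                    10000,
                                                                    10),
                              baseline_year = NULL, resample_offset = TRUE,
                              offset_seed = NULL, fix = NULL) {
  des <- build_design(referrals, baseline_year)
  dat <- des$data
  X <- des$X
  n <- nrow(X); p <- ncol(X)
  y <- dat$y
  areas <- sort(unique(dat$area_id))
  N <- length(areas)
  ai <- match(dat$area_id, areas)

  # offset draw matrix restricted to the referral cells
  if (inherits(offset, "adjusted_denominator")) {
    cell_key <- paste(offset$cells$area_id, offset$cells$year)
    idx <- match(paste(dat$area_id, dat$year), cell_key)
    if (anyNA(idx)) {
      stop("offset lacks draws for some referral cells", call. = FALSE)
    }
    O <- offset$draws[, idx, drop = FALSE]
  } else {
    O <- matrix(offset, nrow = 1)
  }
  if (any(O <= 0)) {
    stop("fit error: offsets must be positive in every cell", call. = FALSE)
  }
  logO <- log(O)
  o_med <- apply(logO, 2, stats::median)

  # ML Poisson fit supplies the starting point and proposal geometry
  glm0 <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::poisson(), offset = o_med))
  gamma <- glm0$coefficients
  gamma[!is.finite(gamma)] <- 0
  w <- glm0$weights
  info <- crossprod(X * sqrt(w))
  prop_chol <- tryCatch(chol(solve(info + diag(1e-8, p))),
                        error = function(e) diag(1e-3, p))

  fixed <- function(nm) !is.null(fix[[nm]])
  kappa2 <- if (fixed("kappa2")) fix$kappa2 else 0.02
  z <- if (fixed("z")) fix$z else rep(0, N)
  z_fixed <- fixed("z")
  a0 <- 1; b0 <- 0.01; prior_g_var <- 1e5

  n_keep <- (mcmc$iterations - mcmc$burn_in) %/% mcmc$thinning
  draws <- list(gamma = matrix(NA_real_, n_keep, p,
                               dimnames = list(NULL, colnames(X))),
                kappa2 = numeric(n_keep),
                z = matrix(NA_real_, n_keep, N,
                           dimnames = list(NULL, areas)),
                offset_index = integer(n_keep))

  # offset-index stream drawn up front on its own seed
  if (is.null(offset_seed)) offset_seed <- mcmc$seed + 1L
  oidx <- if (resample_offset && nrow(O) > 1) {
    with_seed(offset_seed,
              sample.int(nrow(O), mcmc$iterations, replace = TRUE))
  } else {
    rep(1L, mcmc$iterations)
  }
  logO_med <- o_med

  sc_g <- 2.38 / sqrt(p); sc_z <- 1
  acc_g <- 0L; try_g <- 0L; acc_z <- 0; try_z <- 0L
  ad_g <- 0L; ad_z <- 0

  set.seed(mcmc$seed)
  eta <- drop(X %*% gamma)
  keep <- 0L
  for (it in seq_len(mcmc$iterations)) {
    lo <- if (resample_offset && nrow(O) > 1) logO[oidx[it], ] else logO_med
    mu_log <- lo + eta + z[ai]

    # -- gamma block -------------------------------------------------------
    g_p <- gamma + sc_g * drop(crossprod(prop_chol, stats::rnorm(p)))
    eta_p <- drop(X %*% g_p)
    mu_log_p <- lo + eta_p + z[ai]
    la <- sum(y * mu_log_p - exp(mu_log_p)) -
      sum(y * mu_log - exp(mu_log)) +
      (sum(gamma^2) - sum(g_p^2)) / (2 * prior_g_var)
    try_g <- try_g + 1L
    if (is.finite(la) && log(stats::runif(1)) < la) {
      gamma <- g_p; eta <- eta_p; mu_log <- mu_log_p
      acc_g <- acc_g + 1L
      if (it <= mcmc$burn_in) ad_g <- ad_g + 1L
    }

    # -- random intercepts (element-wise Metropolis) -----------------------
    if (!z_fixed) {
      z_p <- z + sc_z * stats::rnorm(N)
      base <- lo + eta
      d_lik <- as.vector(
        rowsum(y * (z_p[ai] - z[ai]) -
                 exp(base + z_p[ai]) + exp(base + z[ai]), ai))
      d_pri <- if (kappa2 > 0) (z^2 - z_p^2) / (2 * kappa2) else
        ifelse(z_p == 0, 0, -Inf)
      u <- log(stats::runif(N))
      take <- is.finite(d_lik + d_pri) & u < d_lik + d_pri
      z[take] <- z_p[take]
      acc_z <- acc_z + mean(take); try_z <- try_z + 1L
      if (it <= mcmc$burn_in) ad_z <- ad_z + mean(take)
    }

    # -- kappa2 ------------------------------------------------------------
    if (!fixed("kappa2")) {
      kappa2 <- 1 / stats::rgamma(1, a0 + N / 2, b0 + sum(z^2) / 2)
    }

    # -- adaptation --------------------------------------------------------
    if (it <= mcmc$burn_in && it %% 100 == 0) {
      sc_g <- sc_g * exp(0.7 * (ad_g / 100 - 0.23))
      if (!z_fixed) sc_z <- sc_z * exp(0.7 * (ad_z / 100 - 0.44))
      ad_g <- 0L; ad_z <- 0
    }
    if (it == mcmc$burn_in) { acc_g <- 0L; try_g <- 0L; acc_z <- 0; try_z <- 0L }

    if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thinning == 0) {
      keep <- keep + 1L
      draws$gamma[keep, ] <- gamma
      draws$kappa2[keep] <- kappa2
      draws$z[keep, ] <- z
      draws$offset_index[keep] <- oidx[it]
    }
  }

  structure(list(draws = draws, design = des, area_ids = areas,
                 acceptance = c(gamma = if (try_g) acc_g / try_g else NA,
                                z = if (try_z) acc_z / try_z else NA),
                 resample_offset = resample_offset,
                 config = mcmc, fixed = names(fix)),
            class = "referral_glmm_fit")
}

#' @export
print.referral_glmm_fit <- function(x, ...) {
  cat(sprintf(
    "<referral_glmm_fit> %d areas, %d cells, %d retained draws\n",
    length(x$area_ids), nrow(x$design$X), length(x$draws$kappa2)))
  cat(sprintf("  acceptance: gamma block %.2f, random intercepts %.2f\n",
              x$acceptance["gamma"], x$acceptance["z"]))
  cat(sprintf("  offset %s\n",
              if (x$resample_offset) "resampled each iteration"
              else "fixed at posterior median"))
  invisible(x)
}
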