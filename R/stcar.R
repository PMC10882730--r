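#' MCMC configuration
#'
#' @param iterations Total iterations including burn-in.
#' @param burn_in Iterations discarded before retention begins; adaptive
#'   proposal tuning happens only during burn-in, so retained draws come
#'   from a fixed kernel.
#' @param thinning Keep every `thinning`-th post-burn-in draw.
#' @param seed Integer seed for the sampler's RNG.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 20000, burn_in = 10000, thinning = 10,
                        seed = 1L) {
  stopifnot(iterations > burn_in, burn_in >= 0, thinning >= 1)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 thinning = as.integer(thinning),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Fit the spatio-temporal CAR population model
#'
#' Fits, by MCMC, the Bayesian hierarchical model for official small-area
#' population estimates given routinely collected register covariates:
#' \deqn{\log(P^{NHS}_{it}) \sim N(x_{it}^\top \beta + S_{it}, \sigma^2)}
#' \deqn{S_t \mid S_{t+1} \sim N(\rho_T S_{t+1}, \tau^2 Q(\rho_S, W)^{-1})
#'   \quad (t = 1, \ldots, T)}
#' \deqn{S_{T+1} \sim N(0, \tau^2 Q(\rho_S, W)^{-1})}
#' with `Q` the Leroux precision matrix. The temporal autoregression
#' conditions each year on the *following* one: the registers are extracted
#' retrospectively, making the most recent year the most accurate, with
#' error accumulating backwards in time. Covariates are an intercept, the
#' log register (CDW) count, a linear time index and the proportion of the
#' area's population registered at non-sharing practices.
#'
#' Cells with `p_nhs = NA` (the unpublished early years) are treated as
#' missing responses and redrawn at every iteration from the posterior
#' predictive distribution `N(x'beta + S, sigma^2)`, yielding a full
#' posterior sample for each missing cell.
#'
#' The Gaussian part of the model is updated as one block: `beta` is drawn
#' from its conditional with the whole random-effect field integrated out,
#' then `S` jointly from its exact Gaussian full conditional. Both draws
#' use the Kronecker eigenstructure of the space-time prior precision
#' `(A(rho_t) %x% Q(rho_s)) / tau^2` — `Q` shares eigenvectors with the
#' graph Laplacian and the temporal autoregression matrix `A` is
#' tridiagonal — so every solve is diagonal after two small orthogonal
#' transforms. This blocked update is what keeps the sampler mixing when
#' the intercept and time covariate are partially confounded with the mean
#' and trend of `S` (a single-site scheme stalls on that ridge). `sigma2`
#' and `tau2` are conjugate inverse-gamma Gibbs draws, and `rho_s`, `rho_t`
#' adaptive random-walk Metropolis on the logit scale (step tuned during
#' burn-in towards an acceptance rate of 0.4; proposals at `rho_s = 1` have
#' a singular precision and are rejected). Priors: `beta ~ N(0, 1e5)`
#' elementwise, `sigma2, tau2 ~ Inverse-Gamma(1, 0.01)`, `rho_s, rho_t ~
#' Uniform(0, 1)`.
#'
#' @param panel Population panel tibble with columns `area_id`, `year`,
#'   `p_cdw`, `p_nhs` (NA allowed), `r_cdw`, `nonsharing_prop`.
#' @param lattice The matching `area_lattice`; `panel` must contain exactly
#'   one row per area-year.
#' @param mcmc An [mcmc_config()].
#' @param fix Optional named list pinning any of `beta`, `sigma2`, `tau2`,
#'   `rho_s`, `rho_t` at known values (their updates are skipped) — used by
#'   oracle and calibration tests.
#' @return An object of class `stcar_fit` with elements `draws` (matrices
#'   of retained draws: `beta`, `sigma2`, `tau2`, `rho_s`, `rho_t`, `S`
#'   with one column per area-year cell, `log_p_nhs_mis` with one column
#'   per missing cell), `missing` (tibble of the imputed cells), `panel`,
#'   `years`, `area_ids`, `acceptance` (post-adaptation Metropolis rates),
#'   and `config`.
#' @seealso [adjust_denominator()], [tidy.stcar_fit()]
#' @export
fit_stcar <- function(panel, lattice, mcmc = mcmc_config(), fix = NULL) {
  N <- n_areas(lattice)
  years <- sort(unique(panel$year))
  Tn <- length(years)
  panel <- panel[order(match(panel$year, years),
                       match(panel$area_id, lattice$area_ids)), ]
  if (nrow(panel) != N * Tn || anyNA(match(panel$area_id,
                                           lattice$area_ids))) {
    stop("panel must hold exactly one row per lattice area and year",
         call. = FALSE)
  }
  all_fixed <- all(c("beta", "sigma2", "tau2", "rho_s", "rho_t") %in%
                     names(fix))
  obs_years <- unique(panel$year[!is.na(panel$p_nhs)])
  if (length(obs_years) < 3 && !all_fixed) {
    stop("need p_nhs observed for at least 3 years", call. = FALSE)
  }

  X <- stage1_design(panel)
  p <- ncol(X)
  y <- log(panel$p_nhs)
  miss <- which(is.na(y))
  y[miss] <- mean(y, na.rm = TRUE)       # initial fill, overwritten below

  L <- diag(rowSums(lattice$W)) - lattice$W   # graph Laplacian
  EL <- eigen(L, symmetric = TRUE)
  lambda <- EL$values
  V <- EL$vectors

  fixed <- function(nm) !is.null(fix[[nm]])
  # start from the observed-cell OLS fit so the first posterior-predictive
  # imputations of the unpublished years are on the right scale
  obs <- setdiff(seq_along(y), miss)
  ols <- stats::lm.fit(X[obs, , drop = FALSE], y[obs])
  beta <- if (fixed("beta")) fix$beta else ols$coefficients
  sigma2 <- if (fixed("sigma2")) fix$sigma2 else
    max(stats::var(ols$residuals), 1e-6)
  tau2 <- if (fixed("tau2")) fix$tau2 else 0.01
  rho_s <- if (fixed("rho_s")) fix$rho_s else 0.5
  rho_t <- if (fixed("rho_t")) fix$rho_t else 0.5
  S <- matrix(0, N, Tn)

  a0 <- 1; b0 <- 0.01; prior_beta_var <- 1e5

  n_keep <- (mcmc$iterations - mcmc$burn_in) %/% mcmc$thinning
  draws <- list(beta = matrix(NA_real_, n_keep, p,
                              dimnames = list(NULL, colnames(X))),
                sigma2 = numeric(n_keep), tau2 = numeric(n_keep),
                rho_s = numeric(n_keep), rho_t = numeric(n_keep),
                S = matrix(NA_real_, n_keep, N * Tn),
                log_p_nhs_mis = matrix(NA_real_, n_keep, length(miss)))

  step_s <- 0.5; step_t <- 0.5
  acc <- c(rho_s = 0L, rho_t = 0L); try_n <- c(rho_s = 0L, rho_t = 0L)
  acc_adapt <- c(rho_s = 0L, rho_t = 0L)

  logdetQ <- function(r) sum(log(r * lambda + 1 - r))
  # temporal autoregression precision: tridiagonal, reverse-order AR(1)
  Amat <- function(r) {
    if (Tn == 1) return(matrix(1, 1, 1))
    A <- diag(c(1, rep(1 + r^2, Tn - 1)))
    for (t in seq_len(Tn - 1)) { A[t, t + 1] <- -r; A[t + 1, t] <- -r }
    A
  }

  # Marginal log-posterior of (rho_s, rho_t) given y, sigma2, tau2, with S
  # (and beta unless fixed) integrated out. In the basis of the Laplacian
  # eigenvectors V and the eigenvectors of A(rho_t), the marginal covariance
  # sigma2 I + tau2 (A %x% Q)^-1 is diagonal with entries
  # sigma2 + tau2 / (alpha_j q_i), so determinants and quadratic forms are
  # elementwise operations after two small orthogonal transforms.
  beta_free <- !fixed("beta")
  marg_logpost <- function(rho_s_, Yt, Xt, alpha) {
    qv <- rho_s_ * lambda + 1 - rho_s_
    if (any(qv <= 0)) return(-Inf)
    dvar <- sigma2 + tau2 / outer(qv, alpha)
    w <- 1 / as.vector(dvar)
    ld <- sum(log(dvar))
    if (beta_free) {
      Aq <- crossprod(Xt, Xt * w)
      bq <- crossprod(Xt, as.vector(Yt) * w)
      M <- Aq + diag(p) / prior_beta_var
      Rm <- tryCatch(chol((M + t(M)) / 2), error = function(e) NULL)
      if (is.null(Rm)) return(-Inf)
      quad <- sum(as.vector(Yt)^2 * w) -
        sum(forwardsolve(t(Rm), bq)^2)
      -0.5 * (ld + 2 * sum(log(diag(Rm))) + p * log(prior_beta_var) + quad)
    } else {
      r <- as.vector(Yt) - drop(Xt %*% beta)
      -0.5 * (ld + sum(r^2 * w))
    }
  }

  set.seed(mcmc$seed)
  keep <- 0L
  for (it in seq_len(mcmc$iterations)) {
    # -- posterior-predictive imputation of unpublished years --------------
    if (length(miss)) {
      eta <- drop(X %*% beta) + as.vector(S)
      y[miss] <- eta[miss] + stats::rnorm(length(miss), 0, sqrt(sigma2))
    }
    Ym <- matrix(y, N, Tn)

    # transforms under the current temporal eigenbasis
    EA <- eigen(Amat(rho_t), symmetric = TRUE)
    VA <- EA$vectors
    tf <- function(M) crossprod(V, M) %*% VA
    Yt <- tf(Ym)
    Xt <- vapply(seq_len(p),
                 function(k) as.vector(tf(matrix(X[, k], N, Tn))),
                 numeric(N * Tn))

    # -- rho_s | y, sigma2, tau2 (beta, S integrated out) ------------------
    if (!fixed("rho_s")) {
      th_p <- stats::qlogis(rho_s) + stats::rnorm(1, 0, step_s)
      r_p <- stats::plogis(th_p)
      log_acc <- marg_logpost(r_p, Yt, Xt, EA$values) -
        marg_logpost(rho_s, Yt, Xt, EA$values) +
        log(r_p * (1 - r_p)) - log(rho_s * (1 - rho_s))
      try_n["rho_s"] <- try_n["rho_s"] + 1L
      if (is.finite(log_acc) && log(stats::runif(1)) < log_acc) {
        rho_s <- r_p
        acc["rho_s"] <- acc["rho_s"] + 1L
        if (it <= mcmc$burn_in) acc_adapt["rho_s"] <- acc_adapt["rho_s"] + 1L
      }
    }

    # -- rho_t | y, sigma2, tau2 (beta, S integrated out) ------------------
    if (!fixed("rho_t") && Tn > 1) {
      th_p <- stats::qlogis(rho_t) + stats::rnorm(1, 0, step_t)
      r_p <- stats::plogis(th_p)
      EA_p <- eigen(Amat(r_p), symmetric = TRUE)
      VA_p <- EA_p$vectors
      tf_p <- function(M) crossprod(V, M) %*% VA_p
      Yt_p <- tf_p(Ym)
      Xt_p <- vapply(seq_len(p),
                     function(k) as.vector(tf_p(matrix(X[, k], N, Tn))),
                     numeric(N * Tn))
      log_acc <- marg_logpost(rho_s, Yt_p, Xt_p, EA_p$values) -
        marg_logpost(rho_s, Yt, Xt, EA$values) +
        log(r_p * (1 - r_p)) - log(rho_t * (1 - rho_t))
      try_n["rho_t"] <- try_n["rho_t"] + 1L
      if (is.finite(log_acc) && log(stats::runif(1)) < log_acc) {
        rho_t <- r_p
        EA <- EA_p; VA <- VA_p; Yt <- Yt_p; Xt <- Xt_p
        tf <- tf_p
        acc["rho_t"] <- acc["rho_t"] + 1L
        if (it <= mcmc$burn_in) acc_adapt["rho_t"] <- acc_adapt["rho_t"] + 1L
      }
    }

    itf <- function(M) V %*% tcrossprod(M, VA)
    qv <- rho_s * lambda + 1 - rho_s
    D <- outer(qv, EA$values) / tau2 + 1 / sigma2

    # -- beta | y, hyperparameters (S integrated out) ----------------------
    if (beta_free) {
      # Sigma^-1 = I/sig2 - G/sig2^2, applied in the diagonal basis
      dvar <- sigma2 + tau2 / outer(qv, EA$values)
      w <- 1 / as.vector(dvar)
      Pb <- crossprod(Xt, Xt * w) + diag(p) / prior_beta_var
      Pb <- (Pb + t(Pb)) / 2
      bb <- crossprod(Xt, as.vector(Yt) * w)
      Rb <- chol(Pb)
      beta <- drop(backsolve(Rb, forwardsolve(t(Rb), bb) +
                               stats::rnorm(p)))
    }

    # -- S | beta, y (exact joint Gaussian draw) ---------------------------
    Rm <- matrix(y - drop(X %*% beta), N, Tn)
    S <- itf(tf(Rm) / (sigma2 * D) +
               matrix(stats::rnorm(N * Tn), N, Tn) / sqrt(D))
    Svec <- as.vector(S)

    # -- sigma2 | rest -----------------------------------------------------
    if (!fixed("sigma2")) {
      ssr <- sum((as.vector(Rm) - Svec)^2)
      sigma2 <- 1 / stats::rgamma(1, a0 + N * Tn / 2, b0 + ssr / 2)
    }

    # innovations u_t = S_t - rho_t S_{t+1}, u_Tn = S_Tn
    U <- S
    if (Tn > 1) {
      U[, seq_len(Tn - 1)] <- S[, seq_len(Tn - 1)] -
        rho_t * S[, -1, drop = FALSE]
    }

    # -- tau2 | rest -------------------------------------------------------
    if (!fixed("tau2")) {
      qL <- sum(U * (L %*% U)); qI <- sum(U * U)
      qf <- rho_s * qL + (1 - rho_s) * qI
      tau2 <- 1 / stats::rgamma(1, a0 + N * Tn / 2, b0 + qf / 2)
    }

    # -- adaptation (burn-in only) -----------------------------------------
    if (it <= mcmc$burn_in && it %% 100 == 0) {
      rate_s <- acc_adapt["rho_s"] / 100; rate_t <- acc_adapt["rho_t"] / 100
      if (!fixed("rho_s")) {
        step_s <- step_s * exp(0.5 * (rate_s - 0.4))
      }
      if (!fixed("rho_t")) {
        step_t <- step_t * exp(0.5 * (rate_t - 0.4))
      }
      acc_adapt[] <- 0L
      if (it == mcmc$burn_in) { acc[] <- 0L; try_n[] <- 0L }
    }
    if (it == mcmc$burn_in) { acc[] <- 0L; try_n[] <- 0L }

    if (!all(is.finite(c(beta, sigma2, tau2, S)))) {
      stop("divergent chain: non-finite state at iteration ", it,
           call. = FALSE)
    }

    # -- retention ---------------------------------------------------------
    if (it > mcmc$burn_in && (it - mcmc$burn_in) %% mcmc$thinning == 0) {
      keep <- keep + 1L
      draws$beta[keep, ] <- beta
      draws$sigma2[keep] <- sigma2
      draws$tau2[keep] <- tau2
      draws$rho_s[keep] <- rho_s
      draws$rho_t[keep] <- rho_t
      draws$S[keep, ] <- Svec
      if (length(miss)) draws$log_p_nhs_mis[keep, ] <- y[miss]
    }
  }

  structure(list(
    draws = draws,
    missing = tibble::tibble(cell = miss,
                             area_id = panel$area_id[miss],
                             year = panel$year[miss]),
    panel = panel, years = years, area_ids = lattice$area_ids,
    acceptance = ifelse(try_n > 0, acc / try_n, NA_real_),
    config = mcmc, fixed = names(fix)),
    class = "stcar_fit")
}

#' @export
print.stcar_fit <- function(x, ...) {
  cat(sprintf(
    "<stcar_fit> %d areas x %d years, %d retained draws, %d imputed cells\n",
    length(x$area_ids), length(x$years), length(x$draws$sigma2),
    nrow(x$missing)))
  cat(sprintf("  Metropolis acceptance: rho_s %.2f, rho_t %.2f\n",
              x$acceptance["rho_s"], x$acceptance["rho_t"]))
  invisible(x)
}
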