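# a small panel with no missing years and everything fixable, for oracle
# checks against dense Gaussian algebra
oracle_panel <- function(lattice, years, seed = 1) {
  tr <- synthetic_truth(seed = seed, years = years, n_missing_years = 0,
                        sigma2 = 0.05, tau2 = 0.2, rho_s = 0.6, rho_t = 0.7)
  list(sim = simulate_stcar_panel(lattice, tr), truth = tr)
}

test_that("the random-effect posterior matches the dense Gaussian oracle", {
  # tiny instance, all hyperparameters fixed at truth: the S draws must
  # match the exact multivariate-normal conditional computed densely
  lat <- build_grid_lattice(1, 2)
  op <- oracle_panel(lat, 2014:2016, seed = 2)
  tr <- op$truth
  fit <- fit_stcar(op$sim$panel, lat, mcmc_config(6000, 1000, 1, seed = 3),
                   fix = list(beta = tr$beta, sigma2 = tr$sigma2,
                              tau2 = tr$tau2, rho_s = tr$rho_s,
                              rho_t = tr$rho_t))
  N <- 2; Tn <- 3
  L <- diag(rowSums(lat$W)) - lat$W
  Q <- tr$rho_s * L + (1 - tr$rho_s) * diag(N)
  A <- diag(c(1, rep(1 + tr$rho_t^2, Tn - 1)))
  for (t in seq_len(Tn - 1)) A[t, t + 1] <- A[t + 1, t] <- -tr$rho_t
  P <- kronecker(A, Q) / tr$tau2 + diag(N * Tn) / tr$sigma2
  pan <- op$sim$panel
  pan <- pan[order(pan$year, pan$area_id), ]
  X <- referralcar:::stage1_design(pan)
  r <- log(pan$p_nhs) - drop(X %*% tr$beta)
  Sig <- solve(P)
  mu <- drop(Sig %*% (r / tr$sigma2))
  for (k in seq_len(N * Tn)) {
    ks <- suppressWarnings(
      stats::ks.test(fit$draws$S[, k], "pnorm", mu[k], sqrt(Sig[k, k])))
    expect_gt(ks$p.value, 0.01)
  }
  expect_equal(colMeans(fit$draws$S), mu, tolerance = 0.05)
})

test_that("with rho_t = 0 each year matches its independent spatial model", {
  lat <- build_grid_lattice(3, 3)
  tr <- synthetic_truth(seed = 5, years = 2014:2016, n_missing_years = 0,
                        sigma2 = 0.05, tau2 = 0.2, rho_s = 0.5, rho_t = 0)
  sim <- simulate_stcar_panel(lat, tr)
  fit <- fit_stcar(sim$panel, lat, mcmc_config(4000, 1000, 1, seed = 6),
                   fix = list(beta = tr$beta, sigma2 = tr$sigma2,
                              tau2 = tr$tau2, rho_s = tr$rho_s,
                              rho_t = 0))
  # exact per-year conditional: (Q/tau2 + I/sig2)^-1 applied to r_t/sig2
  N <- 9
  L <- diag(rowSums(lat$W)) - lat$W
  Q <- tr$rho_s * L + (1 - tr$rho_s) * diag(N)
  Sig_t <- solve(Q / tr$tau2 + diag(N) / tr$sigma2)
  pan <- sim$panel[order(sim$panel$year, sim$panel$area_id), ]
  X <- referralcar:::stage1_design(pan)
  r <- matrix(log(pan$p_nhs) - drop(X %*% tr$beta), N)
  for (t in 1:3) {
    mu_t <- drop(Sig_t %*% (r[, t] / tr$sigma2))
    got <- colMeans(fit$draws$S[, (t - 1) * N + seq_len(N)])
    expect_lt(max(abs(got - unname(mu_t))), 0.06)
  }
})

test_that("chains are reproducible and mix with sensible acceptance rates", {
  fit <- default_stcar_fit()
  expect_true(all(fit$acceptance >= 0.2 & fit$acceptance <= 0.6))
  expect_true(all(fit$draws$rho_s >= 0 & fit$draws$rho_s <= 1))
  expect_true(all(fit$draws$rho_t >= 0 & fit$draws$rho_t <= 1))
  expect_true(all(fit$draws$sigma2 > 0))
  expect_true(all(fit$draws$tau2 > 0))
  # one predictive draw per missing cell per retained iteration
  expect_equal(dim(fit$draws$log_p_nhs_mis),
               c(length(fit$draws$sigma2), 200))

  st <- default_study()
  small <- mcmc_config(400, 200, 2, seed = 9)
  f1 <- fit_stcar(st$panel, st$lattice, small)
  f2 <- fit_stcar(st$panel, st$lattice, small)
  expect_identical(f1$draws, f2$draws)
})

test_that("fit_stcar validates panels and observed-year counts", {
  st <- default_study()
  expect_error(fit_stcar(st$panel[-1, ], st$lattice,
                         mcmc_config(200, 100, 1)),
               "one row per lattice area")
  pan <- st$panel
  pan$p_nhs[pan$year > 2014] <- NA
  expect_error(fit_stcar(pan, st$lattice, mcmc_config(200, 100, 1)),
               "3 years")
})

test_that("denominator adjustment applies the prevalence-rescaling rule", {
  # direct substitution: 100 / 1000 * 1100 = 110
  fit <- default_stcar_fit()
  adj <- default_adjusted()
  pan <- fit$panel
  obs <- !is.na(pan$p_nhs)
  expect_equal(adj$summary$r_hat[obs],
               (pan$r_cdw / pan$p_cdw * pan$p_nhs)[obs])
  # observed cells are identical across draws
  expect_equal(apply(adj$draws[, which(obs)[1:5]], 2, stats::sd), rep(0, 5))
  # imputed cells carry uncertainty and positive values
  mis <- which(!obs)
  expect_true(all(apply(adj$draws[, mis[1:5]], 2, stats::sd) > 0))
  expect_true(all(adj$draws > 0))

  # identity adjustment when the register equals the official count
  tr <- synthetic_truth(seed = 77, n_nonsharing = 0, attrition_rate = 0,
                        attrition_sdlog = 0, relocation_rate = 0,
                        quarter_sdlog = 0, tau2 = 1e-12,
                        n_missing_years = 0)
  lat <- build_grid_lattice(4, 4)
  pop <- simulate_population_panel(lat, tr)
  f <- fit_stcar(pop$panel, lat, mcmc_config(300, 100, 2, seed = 1))
  a <- adjust_denominator(f)
  expect_equal(a$summary$r_hat, pop$panel$r_cdw)

  # Eq. 1 linearity: doubling the official count doubles the adjustment
  pan2 <- pop$panel
  pan2$p_nhs <- pan2$p_nhs * 2
  a2 <- adjust_denominator(f, pan2)
  expect_equal(a2$summary$r_hat, 2 * a$summary$r_hat)

  pan3 <- pop$panel
  pan3$p_cdw[1] <- 0
  expect_error(adjust_denominator(f, pan3), "positive")
})

test_that("adjustment aggregates mirror the under-count-then-recover shape", {
  # with the default error process the adjusted early-year totals exceed
  # the raw register totals, and the percent gap shrinks toward the end
  adj <- default_adjusted()
  tot <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(adj$summary, year <= 2019), year),
    raw = sum(r_cdw), adjusted = sum(r_hat), .groups = "drop")
  cmp <- compare_adjustment(tot$raw, tot$adjusted, tot$year)
  expect_gt(cmp$pct_diff[cmp$year == 2012], cmp$pct_diff[cmp$year == 2019])
  expect_gt(cmp$pct_diff[cmp$year == 2012], 0)
  fit_trend <- stats::coef(stats::lm(pct_diff ~ year, data = cmp))["year"]
  expect_lt(fit_trend, 0)
})
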