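cov_row <- function(year, mbrn = 0, area_id = "A001") {
  tibble::tibble(area_id = area_id, year = year, age65_74 = 17,
                 age75plus = 13, male = 48, distance_km = 8, imd = 16,
                 mbrn_pct = mbrn)
}

test_that("the stage-two design encodes years and interactions correctly", {
  covs <- dplyr::bind_rows(lapply(2012:2019, cov_row))
  des <- build_design(covs)
  expect_equal(colnames(des$X), design_colnames())
  # baseline-year cell with zero coverage: indicators and products all zero
  base <- des$X[des$data$year == 2012, ]
  expect_equal(unname(base[1]), 1)
  expect_true(all(base[7:21] == 0))

  # 2018 cell with full coverage
  covs2 <- dplyr::bind_rows(cov_row(2012), cov_row(2018, mbrn = 100))
  d2 <- build_design(covs2, baseline_year = 2012)
  r18 <- d2$X[d2$data$year == 2018, ]
  expect_equal(unname(r18["year2018"]), 1)
  expect_equal(unname(r18["mbrn"]), 100)
  expect_equal(unname(r18["year2018:mbrn"]), 100)
  expect_true(all(r18[grep("^year(?!2018)", names(r18), perl = TRUE)] == 0))

  # two cells differing only in year differ only in year/interaction columns
  covs3 <- dplyr::bind_rows(cov_row(2014, mbrn = 30), cov_row(2016, mbrn = 30))
  d3 <- build_design(dplyr::bind_rows(cov_row(2012), covs3))
  rows <- d3$X[d3$data$year %in% c(2014, 2016), ]
  same <- colnames(d3$X)[apply(rows, 2, function(cc) cc[1] == cc[2])]
  differ <- setdiff(colnames(d3$X), same)
  expect_setequal(differ, c("year2014", "year2016",
                            "year2014:mbrn", "year2016:mbrn"))

  expect_error(build_design(covs, baseline_year = 2030), "design error")
})

test_that("coverage dichotomisation uses a strict 50% threshold", {
  expect_equal(as.character(classify_mbrn(c(0, 50, 50.1, 100))),
               c("non-MBRN", "non-MBRN", "MBRN", "MBRN"))
  expect_error(classify_mbrn(101), "\\[0, 100\\]")
  expect_error(classify_mbrn(-2), "\\[0, 100\\]")
})

test_that("with no random effects the posterior matches the ML Poisson fit", {
  st <- default_study()
  tr0 <- st$truth
  tr0$kappa2 <- 0
  refs <- simulate_referrals(st$truth_tables$r_true, st$covariates, tr0)
  off <- dplyr::arrange(dplyr::inner_join(
    st$truth_tables$r_true, refs[, c("area_id", "year")],
    by = c("area_id", "year")), year, area_id)$r_true
  fit <- fit_referral_glmm(refs, off, mcmc_config(6000, 2000, 2, seed = 4),
                           fix = list(kappa2 = 1e-12,
                                      z = rep(0, 100)))
  des <- build_design(refs)
  ml <- stats::glm.fit(des$X, des$data$y, family = stats::poisson(),
                       offset = log(off))
  post_mean <- colMeans(fit$draws$gamma)
  post_sd <- apply(fit$draws$gamma, 2, stats::sd)
  ml_sd <- sqrt(diag(chol2inv(chol(crossprod(des$X * sqrt(ml$weights))))))
  # posterior centred on the MLE within Monte-Carlo error
  expect_true(all(abs(post_mean - ml$coefficients) < 4 * ml_sd /
                    sqrt(100) + 0.25 * ml_sd))
  # posterior spread close to the ML standard errors
  expect_true(all(post_sd / ml_sd > 0.7 & post_sd / ml_sd < 1.4))
})

test_that("offset handling is positive, resampled, and stream-separated", {
  st <- default_study()
  adj <- default_adjusted()
  m <- mcmc_config(800, 400, 2, seed = 3)

  # degenerate offset (single draw): resampling cannot matter, and chains
  # with different offset seeds but the same parameter seed are identical
  med_off <- apply(adj$draws, 2, stats::median)
  key <- paste(adj$cells$area_id, adj$cells$year)
  dat <- dplyr::arrange(st$referrals, year, area_id)
  off_vec <- med_off[match(paste(dat$area_id, dat$year), key)]
  f1 <- fit_referral_glmm(st$referrals, off_vec, m, offset_seed = 11)
  f2 <- fit_referral_glmm(st$referrals, off_vec, m, offset_seed = 99)
  expect_identical(f1$draws$gamma, f2$draws$gamma)
  expect_identical(f1$draws$z, f2$draws$z)

  # with genuine draw-to-draw offset variation, different offset seeds give
  # different chains, same seeds identical ones
  g1 <- fit_referral_glmm(st$referrals, adj, m, offset_seed = 11)
  g2 <- fit_referral_glmm(st$referrals, adj, m, offset_seed = 11)
  g3 <- fit_referral_glmm(st$referrals, adj, m, offset_seed = 99)
  expect_identical(g1$draws, g2$draws)
  expect_false(identical(g1$draws$gamma, g3$draws$gamma))

  expect_error(fit_referral_glmm(st$referrals, rep(0, nrow(st$referrals)),
                                 m), "positive")
})

test_that("area labels do not leak into the computation", {
  st <- default_study()
  adj <- default_adjusted()
  m <- mcmc_config(600, 300, 2, seed = 8)
  f1 <- fit_referral_glmm(st$referrals, adj, m)

  # order-preserving relabelling: identical chains, renamed intercepts
  relab <- function(x) sub("^A", "Z", x)
  refs2 <- dplyr::mutate(st$referrals, area_id = relab(area_id))
  adj2 <- adj
  adj2$cells$area_id <- relab(adj2$cells$area_id)
  adj2$summary$area_id <- relab(adj2$summary$area_id)
  f2 <- fit_referral_glmm(refs2, adj2, m)
  expect_identical(unname(f1$draws$z), unname(f2$draws$z))
  expect_identical(colnames(f2$draws$z), relab(colnames(f1$draws$z)))
  expect_identical(f1$draws$gamma, f2$draws$gamma)
})

test_that("glmm acceptance rates sit in the adapted band", {
  fit <- default_glmm_fit()
  expect_gt(fit$acceptance["gamma"], 0.1)
  expect_lt(fit$acceptance["gamma"], 0.5)
  expect_gt(fit$acceptance["z"], 0.2)
  expect_lt(fit$acceptance["z"], 0.65)
  expect_true(all(fit$draws$kappa2 > 0))
})
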