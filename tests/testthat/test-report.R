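test_that("rate-ratio summaries match analytic quantiles", {
  p <- length(design_colnames())
  nm <- design_colnames()

  # all draws zero: RR 1, degenerate interval, insignificant
  g0 <- matrix(0, 200, p, dimnames = list(NULL, nm))
  s0 <- rr_summary(fake_glmm_fit(g0))
  expect_true(all(s0$rr == 1 & s0$lower == 1 & s0$upper == 1))
  expect_false(any(s0$significant))

  # symmetric three-point draws: median RR 1.00
  g1 <- g0
  g1[, "male"] <- rep(log(c(0.99, 1, 1.01)), length.out = 200)
  expect_equal(rr_summary(fake_glmm_fit(g1))$rr[nm == "male"], 1)

  # Gaussian draws: medians and equal-tailed limits match the log-normal
  # quantile function
  set.seed(10)
  g2 <- g0[rep(1, 10000), ]
  g2[, "age65_74"] <- rnorm(10000, 0.0169, 0.004)
  s2 <- rr_summary(fake_glmm_fit(g2))
  row <- s2[s2$parameter == "age65_74", ]
  expect_equal(row$rr, round(stats::qlnorm(0.5, 0.0169, 0.004), 3),
               tolerance = 0.002)
  expect_equal(row$lower, round(stats::qlnorm(0.025, 0.0169, 0.004), 3),
               tolerance = 0.002)
  expect_equal(row$upper, round(stats::qlnorm(0.975, 0.0169, 0.004), 3),
               tolerance = 0.002)
  expect_true(row$significant)

  # significance is invariant to reordering of draws
  g3 <- g2[sample(nrow(g2)), ]
  expect_equal(rr_summary(fake_glmm_fit(g3))$significant, s2$significant)

  expect_error(rr_summary(fake_glmm_fit(g0[1:50, , drop = FALSE])),
               "100 retained draws")
})

test_that("percent change converts rate ratios to narrative form", {
  expect_equal(percent_change(1.017), 1.7)
  expect_equal(percent_change(1.005), 0.5)
  expect_equal(percent_change(1), 0)
  expect_equal(percent_change(0.996), -0.4)
  expect_error(percent_change(0), "positive")
  expect_error(percent_change(-1), "positive")
})

test_that("full-intervention effects combine main and interaction draws", {
  p <- length(design_colnames())
  nm <- design_colnames()
  g0 <- matrix(0, 200, p, dimnames = list(NULL, nm))
  z <- full_intervention_effect(fake_glmm_fit(g0), 2018)
  expect_equal(c(z$pct_change, z$lower, z$upper), c(0, 0, 0))

  # constant combined per-percent RR of 0.995 at delta 100:
  # (0.995^100 - 1) * 100 = -39.4
  g1 <- g0
  g1[, "mbrn"] <- log(0.999)
  g1[, "year2018:mbrn"] <- log(0.995) - log(0.999)
  out <- full_intervention_effect(fake_glmm_fit(g1), 2018)
  expect_equal(out$pct_change, round((0.995^100 - 1) * 100, 1))

  # baseline year uses the main effect only
  base <- full_intervention_effect(fake_glmm_fit(g1), 2012)
  expect_equal(base$pct_change, round((0.999^100 - 1) * 100, 1))
  expect_error(full_intervention_effect(fake_glmm_fit(g1), 2030),
               "unknown study year")

  # agreement with percent_change at delta = 1 and zero interaction
  g2 <- g0
  g2[, "mbrn"] <- 0.0169
  one <- full_intervention_effect(fake_glmm_fit(g2), 2012,
                                  coverage_delta = 1)
  expect_equal(one$pct_change, percent_change(exp(0.0169)))
})

test_that("interaction predictions reduce correctly in degenerate cases", {
  p <- length(design_colnames())
  g0 <- matrix(0, 200, p, dimnames = list(NULL, design_colnames()))
  ip <- interaction_predictions(fake_glmm_fit(g0))
  # gamma all zero: every year and level predicts 100 per 100 patients
  expect_true(all(ip$rate == 100))
  expect_true(all(ip$lower == 100 & ip$upper == 100))

  # identical coverage levels give identical curves
  ip2 <- interaction_predictions(fake_glmm_fit(g0),
                                 coverage_levels = c(0, 0))
  wide <- tidyr::pivot_wider(dplyr::distinct(ip2), names_from = coverage,
                             values_from = c(rate, lower, upper))
  expect_equal(nrow(dplyr::distinct(ip2[, -2])), length(unique(ip2$year)))
})

test_that("annual summaries reproduce printed-table arithmetic", {
  path <- system.file("extdata", "published_annual_referrals.csv",
                      package = "referralcar")
  tot <- readr::read_csv(path, show_col_types = FALSE)
  out <- summarize_annual(tot, n_areas = 204)
  expect_equal(out$avg_per_area[out$year == 2012], 4.75)
  expect_equal(out$avg_per_area[out$year == 2019], 5.93)

  # per-row form with relabelling invariance and the zero case
  refs <- tidyr::expand_grid(area_id = sprintf("A%02d", 1:5),
                             year = 2012:2013)
  refs$y <- seq_len(nrow(refs))
  s1 <- summarize_annual(refs)
  refs2 <- dplyr::mutate(refs, area_id = sample(area_id))
  expect_equal(summarize_annual(refs2)$total, s1$total)
  refs$y <- 0
  expect_true(all(summarize_annual(refs)$avg_per_area == 0))
  expect_error(summarize_annual(tot), "n_areas")
})

test_that("adjustment comparisons report signed one-decimal percent gaps", {
  out <- compare_adjustment(c(22803, 30902), c(26293, 31715),
                            years = c(2012, 2019))
  expect_equal(out$pct_diff, c(15.3, 2.6))
  expect_equal(compare_adjustment(100, 100)$pct_diff, 0)
  expect_error(compare_adjustment(0, 10), "positive")
})

test_that("plot builders return ggplot objects", {
  st <- default_study()
  expect_s3_class(autoplot(cdw_error_summary(st$panel)), "ggplot")
  p <- length(design_colnames())
  g <- matrix(rnorm(200 * p, 0, 0.001), 200, p,
              dimnames = list(NULL, design_colnames()))
  fit <- fake_glmm_fit(g)
  expect_s3_class(autoplot(rr_summary(fit)), "ggplot")
  expect_s3_class(autoplot(interaction_predictions(fit)), "ggplot")
})

test_that("tidiers summarise fitted objects", {
  fit1 <- default_stcar_fit()
  td <- tidy(fit1)
  expect_true(all(c("beta_intercept", "sigma2", "tau2", "rho_s", "rho_t")
                  %in% td$term))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  g1 <- glance(fit1)
  expect_equal(g1$n_imputed_cells, 200)

  fit2 <- default_glmm_fit()
  td2 <- tidy(fit2)
  expect_equal(nrow(td2), 22)
  g2 <- glance(fit2)
  expect_true(g2$kappa2 > 0)
})
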