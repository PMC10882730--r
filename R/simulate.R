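#' Ground-truth configuration for a synthetic referral study
#'
#' Bundles every generating parameter of the synthetic-study machinery: the
#' spatio-temporal error process distorting the routinely collected (CDW)
#' registers, the practice-register structure behind the official (NHS
#' Digital style) population estimates, disease prevalence, and the
#' stage-two referral model truth. Identical configuration and seed always
#' reproduce the identical study.
#'
#' Defaults are sized to the motivating study area: around 1,200 adults per
#' area, a dozen practices serving a 100-area lattice over the study years
#' 2012--2019 plus one extra year used only to stabilise prediction, CRD
#' prevalence near 13%, a register error whose magnitude compounds for each
#' retrospective year (the registers are extracted retrospectively, so the
#' most recent year is the most accurate), and stage-two effects on the
#' scale of per-percentage-point rate ratios close to 1.
#'
#' @param years Integer vector of register years; the last is the extra
#'   post-study year, so study years are `head(years, -1)`.
#' @param n_missing_years Official estimates are dropped for this many of
#'   the earliest years (unpublished small-area data).
#' @param n_practices,n_nonsharing,n_mbrn Number of GP practices, how many
#'   of them do not share records with the CDW, and how many joined the 2017
#'   intervention network (chosen as a spatially clustered set).
#' @param base_pop_meanlog,base_pop_sdlog Log-normal parameters of each
#'   area's baseline adult population.
#' @param pop_growth Mean annual relative population growth.
#' @param attrition_rate Multiplicative register attrition per retrospective
#'   year: a year lagging `k` years behind the final register year is scaled
#'   by `(1 - attrition_rate)^k` before noise (a log-normal factor with
#'   median 1, so the median percent error is exactly that power).
#' @param attrition_sdlog Log-sd of the attrition noise per retrospective
#'   year (error variance grows back in time).
#' @param relocation_rate Per-retrospective-year fraction of an area's
#'   register misassigned to a uniformly chosen queen-contiguous neighbour
#'   (current-address-only recording).
#' @param quarter_sdlog Log-sd of quarterly register count noise.
#' @param sigma2,tau2,rho_s,rho_t Stage-one truth: residual variance of the
#'   log official count, conditional variance and spatial/temporal
#'   dependency of the spatio-temporal CAR error field.
#' @param beta Stage-one regression truth for the design (intercept, log CDW
#'   count, time index, non-sharing proportion) used by
#'   [simulate_stcar_panel()].
#' @param prevalence_mean,prevalence_conc Beta-distributed per-area CRD
#'   prevalence (mean and concentration).
#' @param gamma Named stage-two truth vector on the log rate-ratio scale, in
#'   the column order of [build_design()]. The default mirrors a realistic
#'   fitted table: small positive demographic effects, year effects near
#'   null, and intervention-by-year interactions reaching about
#'   `log(0.995)` per coverage percentage point by the final year.
#' @param kappa2 Variance of the area random intercepts in stage two.
#' @param seed Integer master seed.
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(years = 2012:2020,
                            n_missing_years = 2,
                            n_practices = 12,
                            n_nonsharing = 1,
                            n_mbrn = 5,
                            base_pop_meanlog = log(1150),
                            base_pop_sdlog = 0.22,
                            pop_growth = 0.005,
                            attrition_rate = 0.02,
                            attrition_sdlog = 0.012,
                            relocation_rate = 0.01,
                            quarter_sdlog = 0.004,
                            sigma2 = 2e-3,
                            tau2 = 0.015,
                            rho_s = 0.8,
                            rho_t = 0.7,
                            beta = c(intercept = 0.5, log_p_cdw = 0.93,
                                     time = 0.004, nonsharing = -0.5),
                            prevalence_mean = 0.13,
                            prevalence_conc = 150,
                            gamma = default_gamma(utils::head(years, -1)),
                            kappa2 = 0.023,
                            seed = 1L) {
  stopifnot(length(years) >= 2, n_missing_years >= 0,
            n_practices >= 2, n_nonsharing >= 0, n_mbrn >= 1,
            attrition_rate >= 0, attrition_rate < 1,
            relocation_rate >= 0, relocation_rate < 1,
            prevalence_mean > 0, prevalence_mean < 1,
            rho_s >= 0, rho_s < 1, rho_t >= 0, rho_t <= 1,
            sigma2 > 0, tau2 > 0, kappa2 >= 0)
  structure(as.list(environment()), class = "synthetic_truth")
}

# Stage-two truth on the log rate-ratio scale. Percent covariates enter on
# the 0-100 scale, so demographic gammas are per-percentage-point effects;
# the intercept is set so that typical covariate values give a referral rate
# of roughly 4.5 per 100 CRD patients.
default_gamma <- function(years = 2012:2019) {
  yr <- years[-1]
  yr_fx <- log(c(0.965, 0.991, 1.030, 1.091, 1.049, 0.975, 0.961))
  int_fx <- log(c(0.998, 0.999, 0.998, 0.999, 0.999, 0.996, 0.995))
  k <- seq_along(yr)
  c(intercept = -4.27,
    age65_74 = log(1.017), age75plus = log(1.009), male = log(1.016),
    distance_km = log(1.005), imd = log(0.998),
    stats::setNames(yr_fx[k], sprintf("year%d", yr)),
    mbrn = log(1.001),
    stats::setNames(int_fx[k], sprintf("year%d:mbrn", yr)))
}

#' Simulate practice registers and the resulting population panel
#'
#' Builds a synthetic collection of GP practice registers over a lattice and
#' derives from them both the official population estimates (via
#' [nhs_population_estimate()], i.e. LSOA-at-practice counts times each
#' practice's adult fraction, summed over practices and averaged over
#' quarterly releases) and the distorted routinely collected (CDW) counts.
#' The CDW distortion applies, in order: (a) removal of practices outside
#' the data-sharing agreement, creating spatially correlated gaps; (b) a
#' spatially and temporally correlated multiplicative error field drawn from
#' the spatio-temporal CAR prior; (c) multiplicative attrition compounding
#' per retrospective year (registration end dates are proxied, so error
#' accumulates back in time); and (d) misassignment of a fraction of
#' residents to a neighbouring area (only current addresses are recorded).
#' Official estimates are then masked for the earliest
#' `truth$n_missing_years` years.
#'
#' With all error rates zero and every practice sharing, the CDW counts
#' equal the official estimates exactly.
#'
#' @param lattice An `area_lattice`.
#' @param truth A [synthetic_truth()] configuration.
#' @return A list with `registers` (list: `practices` tibble, `register`
#'   tibble of practice x area x year x quarter counts with the practice
#'   adult fraction), `panel` (tibble `area_id`, `year`, `p_cdw`, `p_nhs`,
#'   `r_cdw`, `nonsharing_prop`), and `truth_tables` (true adult populations
#'   `a_true`, true CRD counts `r_true`, per-area `prevalence`, the error
#'   field `S`).
#' @export
simulate_population_panel <- function(lattice, truth = synthetic_truth()) {
  with_seed(truth$seed, simulate_population_panel_(lattice, truth))
}

simulate_population_panel_ <- function(lattice, truth) {
  N <- n_areas(lattice)
  years <- truth$years
  Tn <- length(years)
  coords <- lattice$coords
  if (is.null(coords)) stop("lattice must carry grid coordinates")

  # --- true adult populations ---------------------------------------------
  base <- pmax(700, round(stats::rlnorm(N, truth$base_pop_meanlog,
                                        truth$base_pop_sdlog)))
  growth <- stats::rnorm(N, truth$pop_growth, 0.003)
  a_true <- outer(base, seq_len(Tn) - 1,
                  function(b, k) b * (1 + growth)^k)
  a_true <- round(a_true)
  dimnames(a_true) <- list(lattice$area_ids, years)

  # --- practices and their catchments -------------------------------------
  pr <- simulate_practices(lattice, truth)
  share <- pr$share                       # N x P area-by-practice shares

  # --- quarterly registers -------------------------------------------------
  # Register counts are all-age: area adults at practice / practice adult
  # fraction, with small quarterly noise.
  reg <- tidyr::expand_grid(practice_id = pr$practices$practice_id,
                            area_id = lattice$area_ids,
                            year = years, quarter = 1:4)
  ai <- match(reg$area_id, lattice$area_ids)
  ti <- match(reg$year, years)
  pi_ <- match(reg$practice_id, pr$practices$practice_id)
  frac <- pr$practices$frac_25plus[pi_]
  mu <- a_true[cbind(ai, ti)] * share[cbind(ai, pi_)] / frac
  reg$count <- round(mu * stats::rlnorm(nrow(reg), 0, truth$quarter_sdlog))
  reg$frac_25plus <- frac
  reg <- dplyr::filter(reg, .data$count > 0)
  registers <- list(practices = pr$practices, register = reg)

  # --- official estimates (full registers) --------------------------------
  nhs <- nhs_population_estimate(registers, lattice$area_ids)

  # --- CDW counts: sharing practices only, then distortion ----------------
  sharing_ids <- pr$practices$practice_id[pr$practices$in_cdw]
  cdw_reg <- list(practices = pr$practices,
                  register = dplyr::filter(reg, .data$practice_id %in%
                                             sharing_ids))
  cdw_base <- nhs_population_estimate(cdw_reg, lattice$area_ids)

  S <- simulate_stcar_field(lattice, Tn, truth$tau2, truth$rho_s,
                            truth$rho_t)
  retro <- rev(seq_len(Tn)) - 1           # years behind the final register
  cdw_wide <- tidyr::pivot_wider(cdw_base, names_from = "year",
                                 values_from = "estimate")
  cdw_wide <- cdw_wide[match(lattice$area_ids, cdw_wide$area_id), ]
  p_cdw <- as.matrix(cdw_wide[, -1])
  for (t in seq_len(Tn)) {
    k <- retro[t]
    noise <- stats::rlnorm(N, 0, truth$attrition_sdlog * sqrt(k))
    p_cdw[, t] <- p_cdw[, t] * (1 - truth$attrition_rate)^k *
      exp(S[, t]) * noise
  }
  # address misassignment between queen neighbours, compounding back in time
  if (truth$relocation_rate > 0) {
    Wn <- lattice$W
    for (t in seq_len(Tn)) {
      fr <- 1 - (1 - truth$relocation_rate)^retro[t]
      if (fr == 0) next
      moved <- p_cdw[, t] * fr
      p_cdw[, t] <- p_cdw[, t] - moved
      for (i in seq_len(N)) {
        nb <- which(Wn[i, ] > 0)
        dest <- if (length(nb) == 1) nb else sample(nb, 1)
        p_cdw[dest, t] <- p_cdw[dest, t] + moved[i]
      }
    }
  }
  p_cdw <- round(p_cdw)
  if (any(p_cdw <= 0)) {
    stop("generation error: non-positive CDW population produced; ",
         "reduce error rates or increase populations", call. = FALSE)
  }

  # --- prevalence and CRD counts ------------------------------------------
  prev <- stats::rbeta(N, truth$prevalence_mean * truth$prevalence_conc,
                       (1 - truth$prevalence_mean) * truth$prevalence_conc)
  r_true <- round(prev * a_true)
  r_cdw <- pmin(round(prev * p_cdw), p_cdw)

  # --- non-sharing proportion (from the official-side registers) ----------
  nonshare <- reg |>
    dplyr::mutate(adults = .data$count * .data$frac_25plus,
                  shared = .data$practice_id %in% sharing_ids) |>
    dplyr::group_by(.data$area_id, .data$year) |>
    dplyr::summarise(nonsharing_prop = sum(.data$adults[!.data$shared]) /
                       sum(.data$adults), .groups = "drop")

  nhs_wide <- tidyr::pivot_wider(nhs, names_from = "year",
                                 values_from = "estimate")
  nhs_wide <- as.matrix(nhs_wide[match(lattice$area_ids,
                                       nhs_wide$area_id), -1])
  missing_years <- years[seq_len(truth$n_missing_years)]
  panel <- tidyr::expand_grid(area_id = lattice$area_ids, year = years) |>
    dplyr::arrange(.data$year, .data$area_id)
  ai <- match(panel$area_id, lattice$area_ids)
  ti <- match(panel$year, years)
  panel$p_cdw <- p_cdw[cbind(ai, ti)]
  panel$p_nhs <- round(nhs_wide[cbind(ai, ti)])
  panel$p_nhs[panel$year %in% missing_years] <- NA_real_
  panel$r_cdw <- r_cdw[cbind(ai, ti)]
  panel <- dplyr::left_join(panel, nonshare, by = c("area_id", "year"))

  list(registers = registers, panel = panel,
       truth_tables = list(
         a_true = a_true,
         r_true = tibble::tibble(
           area_id = rep(lattice$area_ids, Tn),
           year = rep(years, each = N),
           r_true = as.vector(r_true)),
         prevalence = tibble::tibble(area_id = lattice$area_ids,
                                     prevalence = prev),
         S = S))
}

# Practice placement: centres spread over the grid; every area splits its
# register across its three nearest practices with distance-decay weights.
# Intervention practices are a spatially clustered subset.
simulate_practices <- function(lattice, truth) {
  coords <- lattice$coords
  N <- nrow(coords)
  P <- truth$n_practices
  centre_idx <- sample(N, P)
  cx <- coords$col[centre_idx]
  cy <- coords$row[centre_idx]
  d <- sqrt(outer(coords$col, cx, "-")^2 + outer(coords$row, cy, "-")^2)
  aff <- exp(-d / 2.5)
  keep <- t(apply(aff, 1, function(a) {
    top <- order(a, decreasing = TRUE)[seq_len(min(3, P))]
    out <- numeric(length(a)); out[top] <- a[top]; out
  }))
  share <- keep / rowSums(keep)

  # intervention network: a seed practice plus its nearest peers
  seed_pr <- sample(P, 1)
  dp <- sqrt((cx - cx[seed_pr])^2 + (cy - cy[seed_pr])^2)
  mbrn <- order(dp)[seq_len(min(truth$n_mbrn, P))]
  nonshare <- if (truth$n_nonsharing > 0) sample(P, truth$n_nonsharing)
              else integer(0)

  practices <- tibble::tibble(
    practice_id = sprintf("P%02d", seq_len(P)),
    centre_row = cy, centre_col = cx,
    frac_25plus = stats::runif(P, 0.70, 0.80),
    in_cdw = !(seq_len(P) %in% nonshare),
    joined_mbrn_2017 = seq_len(P) %in% mbrn)
  list(practices = practices, share = share)
}

# Draw the spatio-temporal CAR error field: the final time point is drawn
# marginally and earlier ones condition on the following year (registers are
# extracted retrospectively, so error accumulates backwards).
simulate_stcar_field <- function(lattice, Tn, tau2, rho_s, rho_t) {
  Q <- as.matrix(leroux_precision(lattice, rho_s))
  N <- nrow(Q)
  R <- chol(Q)                           # Q = R'R, draw = solve(R, z)*tau
  draw <- function() backsolve(R, stats::rnorm(N)) * sqrt(tau2)
  S <- matrix(0, N, Tn)
  S[, Tn] <- draw()
  for (t in rev(seq_len(Tn - 1))) S[, t] <- rho_t * S[, t + 1] + draw()
  rownames(S) <- lattice$area_ids
  colnames(S) <- NULL
  S
}

#' Simulate a panel directly from the stage-one model
#'
#' Generates `log(p_nhs) = x'beta + S + e` with `S` drawn from the
#' spatio-temporal CAR prior and `e` i.i.d. Gaussian — the exact data
#' generating process assumed by [fit_stcar()]. Used for parameter-recovery
#' and coverage testing, where the mechanistic register simulation of
#' [simulate_population_panel()] would confound model misspecification with
#' sampler error.
#'
#' @param lattice An `area_lattice`.
#' @param truth A [synthetic_truth()]; uses `years`, `n_missing_years`,
#'   `beta`, `sigma2`, `tau2`, `rho_s`, `rho_t`, population and prevalence
#'   settings, and `seed`.
#' @param s_zero If `TRUE`, force the error field `S` to zero (pure
#'   regression truth).
#' @return List with `panel` (as for [simulate_population_panel()]) and
#'   `truth_tables` (the realised `S` and the complete `log_p_nhs` matrix
#'   including masked years).
#' @export
simulate_stcar_panel <- function(lattice, truth = synthetic_truth(),
                                 s_zero = FALSE) {
  with_seed(truth$seed, {
    N <- n_areas(lattice)
    years <- truth$years
    Tn <- length(years)
    p_cdw <- round(stats::rlnorm(N, truth$base_pop_meanlog,
                                 truth$base_pop_sdlog))
    p_cdw <- outer(p_cdw, 1 + truth$pop_growth * (seq_len(Tn) - 1)) *
      stats::rlnorm(N * Tn, 0, 0.01)
    p_cdw <- round(p_cdw)
    nonshare <- stats::rbeta(N, 2, 30)
    panel <- tidyr::expand_grid(area_id = lattice$area_ids, year = years) |>
      dplyr::arrange(.data$year, .data$area_id)
    ai <- match(panel$area_id, lattice$area_ids)
    ti <- match(panel$year, years)
    panel$p_cdw <- p_cdw[cbind(ai, ti)]
    panel$nonsharing_prop <- nonshare[ai]
    X <- stage1_design(panel)
    S <- if (s_zero) matrix(0, N, Tn)
         else simulate_stcar_field(lattice, Tn, truth$tau2, truth$rho_s,
                                   truth$rho_t)
    eta <- drop(X %*% truth$beta) + S[cbind(ai, ti)]
    log_p_nhs <- eta + stats::rnorm(nrow(panel), 0, sqrt(truth$sigma2))
    panel$p_nhs <- exp(log_p_nhs)
    prev <- stats::rbeta(N, truth$prevalence_mean * truth$prevalence_conc,
                         (1 - truth$prevalence_mean) * truth$prevalence_conc)
    panel$r_cdw <- pmin(round(prev[ai] * panel$p_cdw), panel$p_cdw)
    full <- matrix(log_p_nhs[order(ti, ai)], N, Tn,
                   dimnames = list(lattice$area_ids, years))
    panel$p_nhs[panel$year %in% years[seq_len(truth$n_missing_years)]] <-
      NA_real_
    list(panel = panel,
         truth_tables = list(S = S, log_p_nhs = full,
                             prevalence = prev))
  })
}

#' Simulate stage-two covariates for the study years
#'
#' Demographic proportions (percent scale), road distance to the nearest
#' hospital (computed from grid coordinates to a small set of hospital
#' sites, in km), a deprivation score, and the intervention coverage percent
#' derived from the practice registers (share of each area's register held
#' by practices that joined the 2017 network, on the 0--100 scale, computed
#' for all years including pre-intervention ones).
#'
#' @param lattice An `area_lattice`.
#' @param registers Register collection from [simulate_population_panel()].
#' @param truth A [synthetic_truth()].
#' @return Tibble with columns `area_id`, `year`, `age65_74`, `age75plus`,
#'   `male`, `distance_km`, `imd`, `mbrn_pct` over the study years.
#' @export
simulate_covariates <- function(lattice, registers,
                                truth = synthetic_truth()) {
  with_seed(truth$seed + 1L, {
    study_years <- utils::head(truth$years, -1)
    N <- n_areas(lattice)
    coords <- lattice$coords
    hosp <- coords[sample(N, 3), c("row", "col")]
    cell_km <- 1.5
    dist <- apply(coords[, c("row", "col")], 1, function(rc) {
      min(sqrt((rc[1] - hosp$row)^2 + (rc[2] - hosp$col)^2)) * cell_km
    })
    age65 <- pmax(5, stats::rnorm(N, 17, 3))
    age75 <- pmax(3, stats::rnorm(N, 13, 3))
    male <- pmin(60, pmax(40, stats::rnorm(N, 48, 1.5)))
    imd <- stats::rlnorm(N, log(16), 0.45)

    mbrn_ids <- registers$practices$practice_id[
      registers$practices$joined_mbrn_2017]
    cov_tbl <- registers$register |>
      dplyr::filter(.data$year %in% study_years) |>
      dplyr::mutate(adults = .data$count * .data$frac_25plus) |>
      dplyr::group_by(.data$area_id, .data$year) |>
      dplyr::summarise(mbrn_pct = 100 *
                         sum(.data$adults[.data$practice_id %in% mbrn_ids]) /
                         sum(.data$adults), .groups = "drop")

    base <- tibble::tibble(area_id = lattice$area_ids,
                           age65_74 = age65, age75plus = age75,
                           male = male, distance_km = dist, imd = imd)
    tidyr::expand_grid(area_id = lattice$area_ids, year = study_years) |>
      dplyr::left_join(base, by = "area_id") |>
      dplyr::left_join(cov_tbl, by = c("area_id", "year")) |>
      dplyr::mutate(mbrn_pct = pmin(100, pmax(0, dplyr::coalesce(
        .data$mbrn_pct, 0)))) |>
      dplyr::arrange(.data$year, .data$area_id)
  })
}

#' Simulate referral counts from the stage-two model
#'
#' Draws area random intercepts `Z_i ~ N(0, kappa2)` and referral counts
#' `Y_it ~ Poisson(R_it * exp(d_it' gamma + Z_i))`, where `R_it` are the
#' TRUE (undistorted) CRD patient counts — the generative twin of the model
#' fitted by [fit_referral_glmm()].
#'
#' @param r_true Tibble `area_id`, `year`, `r_true` of true CRD counts for
#'   the study years (e.g. `truth_tables$r_true` from
#'   [simulate_population_panel()]).
#' @param covariates Covariate tibble as from [simulate_covariates()].
#' @param truth A [synthetic_truth()]; uses `gamma`, `kappa2`, `seed`.
#' @return Tibble `area_id`, `year`, `y` joined with the covariates, plus
#'   attribute `"z_true"` holding the drawn intercepts.
#' @export
simulate_referrals <- function(r_true, covariates,
                               truth = synthetic_truth()) {
  with_seed(truth$seed + 2L, {
    study_years <- sort(unique(covariates$year))
    dat <- covariates |>
      dplyr::inner_join(r_true, by = c("area_id", "year")) |>
      dplyr::arrange(.data$year, .data$area_id)
    des <- build_design(dat, baseline_year = study_years[1])
    if (!identical(colnames(des$X), names(truth$gamma))) {
      stop("truth$gamma names do not match the design columns: ",
           paste(colnames(des$X), collapse = ", "), call. = FALSE)
    }
    areas <- sort(unique(dat$area_id))
    z <- stats::rnorm(length(areas), 0, sqrt(truth$kappa2))
    names(z) <- areas
    mu <- dat$r_true * exp(drop(des$X %*% truth$gamma) + z[dat$area_id])
    if (any(!is.finite(mu))) {
      stop("generation error: non-finite Poisson mean", call. = FALSE)
    }
    out <- dat
    out$y <- stats::rpois(nrow(dat), mu)
    attr(out, "z_true") <- z
    out
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_population_panel()],
#' [simulate_covariates()] and [simulate_referrals()] under one
#' configuration.
#'
#' @param lattice An `area_lattice`; default 10 x 10 queen grid.
#' @param truth A [synthetic_truth()].
#' @return List of class `synthetic_study` with elements `lattice`,
#'   `registers`, `panel`, `covariates`, `referrals`, `truth`,
#'   `truth_tables`.
#' @export
simulate_study <- function(lattice = build_grid_lattice(10, 10),
                           truth = synthetic_truth()) {
  pop <- simulate_population_panel(lattice, truth)
  covs <- simulate_covariates(lattice, pop$registers, truth)
  refs <- simulate_referrals(pop$truth_tables$r_true, covs, truth)
  structure(list(lattice = lattice, registers = pop$registers,
                 panel = pop$panel, covariates = covs, referrals = refs,
                 truth = truth, truth_tables = pop$truth_tables),
            class = "synthetic_study")
}

#' Write a synthetic study to plain-text fixtures
#'
#' Emits the full study as CSV panels plus a YAML file recording every
#' generating parameter, so a study can be regenerated or consumed by the
#' pipeline without rerunning the generator.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    panel = file.path(dir, "population_panel.csv"),
    referrals = file.path(dir, "referral_panel.csv"),
    register = file.path(dir, "practice_register.csv"),
    practices = file.path(dir, "practices.csv"),
    edges = file.path(dir, "adjacency_edges.csv"),
    ids = file.path(dir, "area_ids.csv"),
    truth = file.path(dir, "truth.yaml"))
  readr::write_csv(study$panel, paths["panel"])
  readr::write_csv(study$referrals, paths["referrals"])
  readr::write_csv(study$registers$register, paths["register"])
  readr::write_csv(study$registers$practices, paths["practices"])
  write_lattice_edges(study$lattice, paths["edges"], paths["ids"])
  tr <- study$truth
  tr$gamma <- as.list(tr$gamma)
  tr$beta <- as.list(tr$beta)
  yaml::write_yaml(unclass(tr), paths["truth"], precision = 12)
  invisible(paths)
}
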