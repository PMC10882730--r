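# Shared fixtures, memoised so expensive simulations and fits are built once
# per test run regardless of how many files use them.
.fixtures <- new.env(parent = emptyenv())

memo_fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# the default-scale synthetic study: 10 x 10 queen lattice, 2012-2020
default_study <- function() {
  memo_fixture("default_study", {
    simulate_study(build_grid_lattice(10, 10), synthetic_truth(seed = 42))
  })
}

default_stcar_fit <- function() {
  memo_fixture("default_stcar_fit", {
    st <- default_study()
    fit_stcar(st$panel, st$lattice, mcmc_config(3000, 1000, 2, seed = 1))
  })
}

default_adjusted <- function() {
  memo_fixture("default_adjusted", adjust_denominator(default_stcar_fit()))
}

default_glmm_fit <- function() {
  memo_fixture("default_glmm_fit", {
    fit_referral_glmm(default_study()$referrals, default_adjusted(),
                      mcmc_config(6000, 2000, 2, seed = 2))
  })
}

# random connected lattice for brute-force oracles: a grid with a random
# subset of queen edges added to a rook backbone
random_lattice <- function(n_max = 25) {
  rows <- sample(2:5, 1)
  cols <- sample(2:(n_max %/% rows), 1)
  build_grid_lattice(rows, cols, sample(c("rook", "queen"), 1))
}

# hand-built referral fit object with prescribed gamma draws, for testing
# the reporting layer independently of MCMC
fake_glmm_fit <- function(gamma_draws, years = 2012:2019,
                          baseline_year = 2012, data = NULL) {
  if (is.null(data)) {
    data <- tibble::tibble(area_id = "A001", year = years,
                           age65_74 = 17, age75plus = 13, male = 48,
                           distance_km = 8, imd = 16, mbrn_pct = 0)
  }
  structure(list(
    draws = list(gamma = gamma_draws,
                 kappa2 = rep(0.02, nrow(gamma_draws)),
                 z = matrix(0, nrow(gamma_draws), 1,
                            dimnames = list(NULL, "A001"))),
    design = list(years = years, baseline_year = baseline_year,
                  data = data),
    area_ids = "A001",
    acceptance = c(gamma = 0.3, z = 0.4),
    resample_offset = FALSE,
    config = mcmc_config(200, 100, 1)),
    class = "referral_glmm_fit")
}

# column names of the stage-two design for the default study years
design_colnames <- function(years = 2012:2019, baseline = 2012) {
  other <- setdiff(years, baseline)
  c("intercept", "age65_74", "age75plus", "male", "distance_km", "imd",
    paste0("year", other), "mbrn", paste0("year", other, ":mbrn"))
}
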