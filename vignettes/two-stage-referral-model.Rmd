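---
title: "Two-stage modelling of outpatient referral rates from error-prone GP registers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage modelling of outpatient referral rates from error-prone GP registers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(referralcar)
```

## The problem

Evaluating an area-level health-service intervention — here, an integrated
respiratory care network that upskills primary care teams to avoid
unnecessary outpatient referrals — requires modelling the *rate* of
referrals per chronic respiratory disease (CRD) patient, not the raw count.
The natural denominator, the number of diagnosed CRD patients in each small
area and year, comes from routinely collected GP registers. Those registers
carry systematic error:

* practices outside the data-sharing agreement are simply absent, creating
  spatially clustered under-counts;
* registration *end* dates are proxied by last contact, so the register
  under-counts more severely the further back in time one looks (data are
  extracted retrospectively; the most recent year is the most accurate);
* only current addresses are stored, so movers are assigned to the wrong
  area for part of their history.

Official small-area GP-registration estimates exist but only from part-way
through the study period, and without an age breakdown at area level.

The package implements a two-stage Bayesian answer:

1. **Stage one** models the official adult population estimates
   \(P^{NHS}_{it}\) given the error-prone register counts, with a
   spatio-temporal conditional autoregressive (CAR) random field capturing
   the structured register error, and imputes the unpublished early years
   from the posterior predictive distribution. The CRD patient count is
   then rescaled by
   \(\hat R_{it} = (R^{CDW}_{it} / P^{CDW}_{it}) \times P^{NHS}_{it}\),
   assuming the register-derived prevalence is representative of the cell.
2. **Stage two** models referral counts
   \(Y_{it} \sim \mathrm{Poisson}(\hat R_{it} \exp(d_{it}^\top\gamma + Z_i))\)
   with independent area intercepts \(Z_i \sim N(0,\kappa^2)\), a year
   factor, intervention coverage percent, and year-by-coverage
   interactions — the interaction terms are the estimate of the
   intervention effect. One stage-one draw is selected uniformly at random
   at *every* MCMC iteration and the offset recomputed, so stage-one
   uncertainty propagates into the stage-two intervals.

The primary data are confidential NHS records, so the package ships a
synthetic-study generator with known ground truth; every claim the test
suite makes is a claim about recovery of known truth or about exact
worked arithmetic on published summary tables.

## Stage one: model and sampler

For areas \(i = 1,\dots,N\) on a lattice with binary neighbourhood matrix
\(W\) and years \(t = 1,\dots,T+1\):

\[
\log(P^{NHS}_{it}) \sim N(x_{it}^\top\beta + S_{it},\ \sigma^2), \qquad
S_t \mid S_{t+1} \sim N(\rho_T S_{t+1},\ \tau^2 Q(\rho_S, W)^{-1}), \qquad
S_{T+1} \sim N(0,\ \tau^2 Q(\rho_S, W)^{-1}),
\]

with the Leroux precision
\(Q(\rho_S, W) = \rho_S(\mathrm{diag}(W1) - W) + (1-\rho_S)I\), which
interpolates between independence (\(\rho_S = 0\)) and the intrinsic CAR
(\(\rho_S = 1\)). The temporal autoregression runs in *reverse* — each year
conditions on the one after it — because the registers are extracted
retrospectively and error accumulates backwards. Covariates are an
intercept, \(\log P^{CDW}_{it}\), a linear time index and the proportion of
the area registered at non-sharing practices. Priors:
\(\beta \sim N(0, 10^5)\) elementwise, \(\sigma^2, \tau^2 \sim
\mathrm{IG}(1, 0.01)\), \(\rho_S, \rho_T \sim U(0,1)\).

### Why the sampler is blocked

The joint prior precision of \(\mathrm{vec}(S)\) is
\((A(\rho_T) \otimes Q(\rho_S))/\tau^2\) with \(A\) tridiagonal, so the
full conditional precision \((A \otimes Q)/\tau^2 + I/\sigma^2\) is
diagonal in the basis formed by the (fixed) eigenvectors of the graph
Laplacian and the eigenvectors of the small matrix \(A\). Every solve,
determinant and draw is therefore an elementwise operation after two small
orthogonal transforms.

This structure matters for correctness, not just speed. The intercept and
time covariate are partially confounded with the mean and trend of \(S\):
a single-site Gibbs scheme (update \(\beta\) given \(S\), then each
\(S_t\) block) cannot traverse that ridge, and in our experiments it
drifted into a degenerate basin where the unidentified mean component of
\(S\) inflates the independence penalty and \(\rho_S\) sticks at 1 — while
an exact marginal-likelihood grid on the same data peaks at the true
\(\rho_S\). The implemented sampler therefore:

* updates \(\rho_S\) and \(\rho_T\) by random-walk Metropolis on the logit
  scale against the **marginal** posterior with both \(\beta\) and \(S\)
  integrated out (closed form in the diagonal basis);
* draws \(\beta\) from its conditional with \(S\) integrated out, then
  \(S\) jointly from its exact Gaussian full conditional — together a
  blocked draw of \((\beta, S)\);
* updates \(\sigma^2\) and \(\tau^2\) by conjugate inverse-gamma Gibbs;
* redraws every missing \(\log P^{NHS}\) cell from
  \(N(x^\top\beta + S, \sigma^2)\) at every iteration (posterior-predictive
  imputation), storing one draw per retained iteration.

Metropolis steps adapt towards a 0.4 acceptance rate during burn-in only;
proposals at \(\rho_S = 1\) have a singular precision and are rejected.
The chain is initialised at the observed-cell least-squares fit: with an
arbitrary start, the first imputations of the missing years are wildly
wrong, which inflates \(\tau^2\) and can trap the chain in the degenerate
\(\rho_S \approx 1\) basin described above.

Defaults are 20,000 iterations, 10,000 burn-in, thinning 10, one chain,
all configurable through `mcmc_config()`.

### Identifiability of the nugget

In the marginal covariance \(\sigma^2 I + \tau^2 (A \otimes Q)^{-1}\) the
nugget \(\sigma^2\) is identified only against the *smallest* random-field
eigen-variances, \(\tau^2/(\alpha_{\max} q_{\max})\). If \(\sigma^2\) lies
below that floor the likelihood is flat along a \(\sigma^2\)–\(\tau^2\)
ridge and no sampler can recover the split. The synthetic defaults
(\(\sigma^2 = 2\times10^{-3}\), i.e. ~4.5% residual sd on the log scale,
against \(\tau^2 = 0.015\), \(\rho_S = 0.8\), \(\rho_T = 0.7\)) keep the
nugget above the floor. Analyses of real registration data whose residual
noise is far smaller than the structured error should expect the same
ridge, and should interpret \(\sigma^2\) and \(\tau^2\) jointly rather
than separately.

## Stage two: referral model

`build_design()` produces the fixed 21-column design: intercept, % adults
aged 65–74, % aged 75+, % male, road distance to the nearest hospital
(km), deprivation score, seven year indicators (baseline is the first
study year), intervention coverage percent (0–100, computed for all years
including pre-intervention ones so baseline differences are absorbed), and
seven year-by-coverage products. Percent covariates stay on the 0–100
scale so each coefficient is a per-percentage-point log rate ratio.

`fit_referral_glmm()` uses blocked random-walk Metropolis for \(\gamma\)
(proposal geometry from the maximum-likelihood Poisson fit, global scale
adapted in burn-in), simultaneous univariate Metropolis for the
conditionally independent \(Z_i\), and conjugate inverse-gamma Gibbs for
\(\kappa^2\) (priors \(\gamma \sim N(0,10^5)\),
\(\kappa^2 \sim \mathrm{IG}(1, 0.01)\)). The offset draw index is
re-selected every iteration, not every thinned sample, and comes from its
own seeded RNG stream: with degenerate (identical) stage-one draws,
changing the offset seed leaves the parameter chain bit-identical, which
the tests assert. Defaults: 30,000 iterations, 10,000 burn-in, thin 10.

Reporting follows the Bayesian workflow: equal-tailed intervals
throughout (the near-symmetric intervals of this model are consistent with
either equal-tailed or highest-density; equal-tailed is simpler and
stated); rate ratios to 3 decimals, percent changes to 1, per-area
averages to 2. `full_intervention_effect()` combines the coverage main
effect with the year's interaction per draw *before* exponentiating and
scaling to the coverage difference — which is why its percent changes do
not equal powers of the rounded tabulated rate ratios. For the
interaction plot, `interaction_predictions()` fixes all other covariates
at their data-set medians and sets the random intercept to its prior mean
of zero (predictions describe a typical area, not a specific one;
marginalising over \(Z\) would widen the bands slightly but not move the
medians).

## The synthetic-study generator

`simulate_study()` emulates the documented data-generating context rather
than resampling any real records:

* **Scale.** 100 areas (a 10×10 queen-contiguity grid), study years
  2012–2019 plus one extra register year, 12 practices — structured like
  the real study area (204 areas, 32 practices) but small enough for
  desk-scale MCMC. Areas hold ~1,200 adults (log-normal, floor 700);
  per-area CRD prevalence is Beta-distributed around 13%.
* **Registers.** Practice catchments are distance-decay shares over the
  grid; quarterly all-age counts with ~0.4% noise; each practice has an
  adult fraction in 0.70–0.80. The official estimate is computed exactly
  as published small-area registration data are: area-at-practice count ×
  practice adult fraction, summed over practices, averaged over the
  year's quarterly releases (`nhs_population_estimate()`).
* **Register error.** Sharing-practice counts are distorted by (a) a
  spatio-temporal CAR field drawn from the stage-one prior (spatially
  clustered over/under-counts), (b) multiplicative attrition of 2% per
  retrospective year with log-normal noise whose scale grows with lag
  (median error is exactly \((1-a)^k\) at lag \(k\)), and (c)
  misassignment of a compounding fraction (1%/year) of residents to a
  random queen neighbour. One of 12 practices is non-sharing. Official
  estimates are masked for 2012–2013.
* **Intervention coverage.** A spatially clustered set of 5 practices is
  flagged as 2017 joiners; per-area coverage percent is the register
  share held by those practices, computed for every study year.
* **Stage-two truth.** \(\gamma\) defaults mirror a realistic fitted
  table: small positive demographic effects (e.g. +1.7%/point for the
  65–74 share), near-null year effects, a near-null coverage main effect,
  and interactions reaching log(0.996) and log(0.995) per coverage point
  in the last two years; \(\kappa^2 = 0.023\). The intercept is set so a
  typical area sees roughly 4.5 referrals per 100 CRD patients.

What the generator does **not** emulate: real polygon geographies,
practice list churn, diagnosis-code filtering, age-structured migration,
or any COVID-era disruption. Passing recovery tests therefore demonstrate
that the estimators are correct and well calibrated *under the stated
error model*, not that the error model matches any particular register.

`simulate_stcar_panel()` additionally generates directly from the
stage-one likelihood (no register mechanics); parameter-recovery and
hold-out coverage tests use it so that sampler error is not confounded
with model misspecification.

## Numerical choices and degenerate inputs

* Moran's I uses the binary, non-row-standardised \(W\) and the classical
  normalising constant, with two-sided permutation p-values
  (\(p = (1 + \#\{|I^*| \ge |I|\})/(n_{\mathrm{perm}}+1)\); default
  9,999 permutations); constant inputs are an error (zero variance).
* The lag-1 temporal autocorrelation is the plug-in estimator whose
  denominator is the full series sum of squares (the `stats::acf()`
  convention); the alternative that divides by the number of covariance
  pairs is not used. Constant series are dropped from the mean with a
  warning.
* Adjustment requires \(P^{CDW} > 0\) in every cell; zero registers make
  the prevalence undefined and raise an error rather than a silent 0/0.
* `classify_mbrn()` uses the strict `> 50%` threshold.
* All generators and samplers take explicit integer seeds; permutation
  and offset-resampling streams are isolated with `with_seed()` so they
  never perturb the caller's RNG state or each other.

## Problem sizes used by the tests and acceptance script

Stage-one recovery runs 20 replicate studies at \(N=100\), \(T+1=9\) with
5,000-iteration chains and checks pooled 95%-interval coverage of
\(\beta, \sigma^2, \tau^2, \rho_S, \rho_T\) at the 90%-of-checks bar;
stage-two recovery does the same for the 21 regression effects and
\(\kappa^2 = 0.023\). The tiny-instance oracle compares \(S\) draws
against dense multivariate-normal algebra at \(N=2\), \(T+1=2\) via
Kolmogorov–Smirnov tests (the draws are exact conditional draws, hence
independent, so the KS test applies directly). Hold-out validation masks
one observed year and requires 90–98% predictive coverage at nominal 95%.
These sizes were chosen as the smallest at which the checks are
statistically meaningful; `scripts/acceptance.R` re-runs the same
computations from scratch under a caller-supplied seed.

## Known limitations

* \(\sigma^2\)/\(\tau^2\) are jointly, not separately, identified when the
  nugget is small (see above).
* The offset-resampling effect on interval width is real but modest
  (a few percent on average at the default scale); detecting it requires
  long chains, and single short chains can show a noise-dominated ratio
  below 1.
* The no-pooling independence assumption on \(Z_i\) follows the source
  model; a spatial prior on \(Z\) is deliberately out of scope.
* Year-by-coverage effects in a single simulated study of 100 areas carry
  wide intervals; individual interaction estimates (especially early
  post-intervention years) can be weak in any one realisation even though
  calibration holds across replicates.
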