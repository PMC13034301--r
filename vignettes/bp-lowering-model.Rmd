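---
title: "Modelling first-trimester blood-pressure lowering and pre-eclampsia risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling first-trimester blood-pressure lowering and pre-eclampsia risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pelower)
```

## The model

pelower implements a competing-risks view of pre-eclampsia (PE) at
first-trimester screening. The latent quantity is the gestational age $g$ at
which a pregnancy would deliver with pre-eclampsia if no other delivery
intervened. Under the model every pregnancy has such a time; pre-eclampsia
is *observed* only when $g$ is small enough to arrive before delivery from
other causes. The personalised distribution of $g$ is

$$ g \sim \mathcal{N}(\mu_0 + \textstyle\sum_j \beta_j x_j,\; \sigma^2), $$

where the $x_j$ are maternal characteristics (chronic hypertension, previous
pre-eclampsia, ethnic group, weight, conception method, ...) and negative
shifts $\beta_j$ move the distribution earlier, i.e. towards higher risk.
Risks by gestational-age band are tail masses of this distribution: the risk
of pre-eclampsia with delivery before 37 weeks is
$P(g < 37 \mid g \ge 24)$, and mass beyond $g_{\max}$ (default 42 weeks)
means no pre-eclampsia before delivery.

Biomarkers update the prior by Bayes' rule. Each marker $k$ — mean arterial
pressure (MAP), uterine artery pulsatility index (UtA-PI), placental growth
factor (PlGF) — enters as a log10 multiple of the median (MoM): the observed
value divided by its expected value for the woman's covariates, from a
per-marker regression. Given $g$, the vector of log10 MoM values is
multivariate normal with covariance $\Sigma$ and piecewise-linear mean

$$ m_k(g) = b_k \, \min(g - g_{0,k},\, 0), $$

so markers are informative about early pre-eclampsia and fade to
uninformative at the changepoint $g_{0,k}$. Defaults give higher MAP and
UtA-PI MoM, and lower PlGF MoM, for earlier $g$ ($b_{MAP}, b_{UtA\text{-}PI} < 0$,
$b_{PlGF} > 0$).

The posterior is computed on a grid (24 to 42 weeks, step 0.05): each cell
carries its exact prior normal mass times the likelihood at the cell
midpoint, plus an atom beyond $g_{\max}$ evaluated at the censored regime
$m_k = 0$; the result is normalised. Cell edges are required to align with
the band cut-offs (32/34/37 weeks), which makes band masses exact for the
prior and keeps midpoint error to about $10^{-6}$ on the band risks
(tested against adaptive quadrature at $10^{-5}$). Missing markers are
marginalised out of the likelihood — the covariance is restricted to the
observed markers — rather than imputed.

### Why these defaults

The published coefficient estimates of the screening model this engine is
structured after are proprietary and not printed in the public literature we
rely on. All coefficients therefore live in a configuration object
(`default_params()`, YAML round-trip via `read_params()`/`write_params()`)
and the shipped values are synthetic defaults with two documented calibration
goals, fixed once:

* the default synthetic cohort reproduces incidences at the scale of a large
  unselected screening population — about 0.8% preterm, 2.1% term and 2.9%
  all pre-eclampsia (prior intercept 63.4 weeks, SD 10 weeks; the realised
  cohort mean of the prior location is about 61.5 weeks once covariate
  shifts are applied);
* blood-pressure marginals land near published strata: roughly 29/13/5/2% of
  women above diastolic 75/80/85/90 mm Hg (MAP residual SD 0.038 log10 MoM,
  blood-pressure model below).

Marker slopes ($-0.005$, $-0.018$, $+0.025$ log10 MoM per week for
MAP/UtA-PI/PlGF) give MoM deviations at 32-34 weeks of roughly +10% MAP,
+40% UtA-PI and $-40$% PlGF relative to term, consistent in magnitude with
first-trimester screening literature. The changepoints default to
$g_{0,k} = g_{\max} = 42$ so the censored atom ($m_k = 0$) is continuous
with the end of the grid.

## The counterfactual intervention

A policy is a pair (threshold $T$, target $t \le T$): women with diastolic
blood pressure strictly above $T$ are treated and their attained diastolic
pressure is modelled as exactly $t$. Systolic pressure falls along with
diastolic at a fixed ratio $\rho$ (default $5.8/4.6 \approx 1.26$, the
systolic/diastolic reduction observed in a randomised trial of tight
blood-pressure control in pregnancy); this linear co-reduction is a stand-in
for the original study's unpublished systolic simulation model. Simulated
systolic values are floored just above diastolic + 5 mm Hg with a warning.
Four named policies are built in: current care (90 → 85) and uniform
threshold-equals-target policies at 85, 80 and 75 mm Hg.

Re-scoring recomputes the MAP MoM from the capped pressures while keeping
the MoM denominator at its pre-treatment covariate expectation (treatment
changes the measurement, not the woman), then recomputes the posterior and
band risks. Untreated pregnancies keep their baseline risks exactly, so the
whole-cohort expected-case reduction equals the treated-subgroup reduction
— an identity the tests assert.

Expected case counts are sums of decimal risks. For expected counts $E_u$
(untreated) and $E_t$ (treated) over $n$ pregnancies the scenario tables
report the relative risk reduction $100 (E_u - E_t)/E_u$, the absolute risk
reduction $100 (E_u - E_t)/n$ and the number needed to treat
$n/(E_u - E_t)$, all computed on unrounded sums and rounded only for
display. (Published table footnotes describe the relative reduction as
treatment-versus-*observed*; the printed values in those tables reproduce
from the expected-versus-treated convention used here.)

## Calibration

Predicted risks are compared with outcomes two ways: a 10-bin equal-count
calibration table, and logistic recalibration at the individual level — the
intercept from a Bernoulli fit with `qlogis(risk)` as a fixed offset
(calibration-in-the-large; 0 is perfect) and the slope from the
two-parameter fit (1 is perfect). Fitting uses iteratively reweighted least
squares via `stats::glm` with a convergence tolerance of 1e-10; risks are
clipped to $[10^{-8}, 1 - 10^{-8}]$ before the logit, with a message when
clipping occurs. Tests check the constant-risk closed form
$\alpha = \mathrm{logit}(f) - \mathrm{logit}(r)$ and recovery of known
offsets and slopes from simulation.

## The synthetic cohort generator

`simulate_cohort()` draws, per pregnancy and in this order: covariates
(marginals matching a large published screening cohort — ethnic mix
72.3/17.3/5.5/2.2/2.6%, 47.1% nulliparous, 1.3% chronic hypertension, median
age 31, median screening gestation 12.7 weeks; weight and height bivariate
with correlation 0.4, all else independent — a documented simplification);
the prior mean; the latent PE delivery time $g_{pe}$ from the truncated
prior; log10 MoM values from the model's own likelihood at $g_{pe}$; raw
markers as MoM times expected value; blood pressure; the other-cause
delivery time from a truncated normal centred at 40.0 weeks (SD 1.4,
range 24-42); and the outcome.

Blood pressure is reconciled with the MAP marker rather than drawn
separately: $sbp = 31 + MAP + \mathcal{N}(0, 5)$ and
$dbp = (3\,MAP - sbp)/2$, so the MAP implied by the stored pressures equals
the generated marker exactly (rare degenerate draws are clamped). This
guarantees the biomarker-outcome dependence the scorer assumes and yields
realistic systolic/diastolic spreads.

Two outcome modes are provided because the scoring model deliberately
ignores competing delivery:

* **`"model"`** (default): pre-eclampsia occurs whenever
  $g_{pe} \le g_{\max}$ — exactly the event whose probability the scorer
  integrates — and the other-cause delivery time is drawn conditional on not
  pre-empting it. Generator and scorer are then self-consistent: summed
  decimal risks match observed incidence and calibration recovers
  intercept 0 / slope 1, which is what the end-to-end tests assert.
* **`"competing"`**: the other-cause time is drawn independently and censors
  pre-eclampsia whenever it comes first. This emulates real cohorts, where a
  scorer that assumes delivery from no other cause over-predicts term
  pre-eclampsia; a test asserts that over-prediction qualitatively.

Passing tests in `"model"` mode therefore show internal consistency of the
pipeline, not real-world accuracy; the `"competing"` mode quantifies the
direction of the bias the simplification introduces.

## Problem sizes and numerical choices

The end-to-end tests and the acceptance script use 50,000-pregnancy cohorts
(scored in a few seconds via a vectorised kernel that shares the likelihood
grid across pregnancies in 5,000-row blocks); distributional unit tests use
2,000-200,000 rows as needed for their standard errors. Stochastic
assertions use 3-standard-error bands under fixed seeds. Degenerate inputs
are rejected with named errors: unknown categorical levels, non-positive
markers, diastolic at or above systolic pressure, singular marker
covariance, empty grids, complete separation in calibration.

## Known limitations

* Coefficients are synthetic defaults, not the published screening model;
  absolute risks from real cohorts require externally fitted parameters via
  the configuration file.
* Covariates are drawn (nearly) independently; real joint structure (e.g.
  weight with ethnic group and chronic hypertension) is not emulated.
* Term pre-eclampsia risk is overestimated when delivery from other causes
  competes (by design, matching the scoring model's assumption); no
  censoring correction is attempted.
* Aspirin prophylaxis, adverse treatment effects, secondary outcomes and
  multi-fetal pregnancies are out of scope.

## A worked example

```{r}
config <- default_generator_config(n = 2000, seed = 42)
cohort <- simulate_cohort(config)
res <- run_scenario(cohort, "t85", config$params)
res$table[res$table$scope == "treated_subgroup" & res$table$band == "all", ]
```
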