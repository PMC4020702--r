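---
title: "Joint known-fate and tag-recovery estimation of harvest rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint known-fate and tag-recovery estimation of harvest rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointharvest)
```

## The problem

The Brownie dead-recovery model estimates annual harvest rates from the
number of tagged animals reported shot in each hunting season after
release. It assumes every tagged animal survives from capture to the
opening of the first season. Many game species are most easily captured
months before the season — deer baited in winter, hen turkeys trapped
January–March — and when pre-season natural mortality is appreciable the
recovery rate estimates the product of survival-to-season and harvest
probability, so the harvest rate is biased low by exactly the pre-season
mortality fraction.

Radio telemetry solves the opposite half of the problem: known-fate
monitoring of transmitter-fitted animals measures pre-season survival
precisely, but transmitters are expensive, so harvest rates estimated
from transmitters alone are imprecise.

`jointharvest` implements the joint model that combines the two: a
staggered-entry Kaplan–Meier known-fate likelihood for monthly pre-season
survival, a Brownie multinomial for reward-tag recoveries in which each
cohort's cell probabilities carry the cumulative tagging-to-harvest
survival \(S_{G}\), and (optionally) a binomial for the seasonal harvest
of transmitter-fitted animals. Because the three data streams are
independent, the joint likelihood is their product.

## Model

For interval (month) \(g\) with \(n_g\) animals at risk, \(d_g\) deaths
and \(c_g\) censored, the known-fate kernel is
\[
\ell_{KM} = \sum_g \left[(n_g - d_g - c_g)\log s_g + d_g \log(1-s_g)\right],
\]
with the closed-form interval MLE \(\hat s_g = 1 - d_g/(n_g - c_g)\).
Censored animals contribute neither death nor survival information in the
interval of censoring; the model assumes censoring is unrelated to fate.

An animal entering in month \(g_0\) must survive months \(g_0,\dots,G\)
(\(G\) = last pre-season month, default 9), so its cumulative
tagging-to-harvest survival is \(S_G = \prod_{g=g_0}^{G} s_g\). Cohorts
tagged later in the winter face fewer monthly hazards — this is exactly
how staggered entry enters the recovery model.

For a cohort of \(N_i\) animals tagged in year \(i\), the expected number
recovered in year \(j\) is
\[
E[R_{ij}] = N_i\, S_{Gi}\, H_j \prod_{k=i}^{j-1} S_k ,
\]
with harvest rates \(H_j\), annual survival rates \(S_k\), and a final
never-recovered cell completing the multinomial. Reward tags are assumed
to make the reporting rate 1, so the recovery rate equals the harvest
rate; the package never estimates reporting, retrieval or kill
probabilities separately. With tag-recovery data alone, \(S_{Gi}\) and
\(H_i\) appear only as a product and are confounded; the known-fate
stream pins down the monthly rates and makes them separately estimable
(`build_parameter_map()` refuses specifications that leave the product
unidentified).

Transmitter-fitted animals available in season \(i\) contribute a
binomial \(h_i \sim \mathrm{Bin}(m_i, H_{ri})\). The radio harvest rate
can be constrained equal to the tag harvest rate or estimated separately;
comparing those two models by AICc is the transmitter-effect test
(`tag_effect_test()`).

## Factor structures and parameter counting

`model_spec()` describes each family's factor structure: monthly survival
by any of month, year, stratum; harvest by year, age, unit, tag type;
annual survival by year, age, unit. Structures are full crossings of the
listed factors over the levels present in the data. (Where a design
mixes a month-by-age survival structure, the full 9 x 2 crossing is used;
additive structures on the link scale are not supported.)

A parameter is free precisely when it appears in at least one likelihood
cell. Three structural rules follow with no special casing:

* a year-varying annual survival for the final year appears in no
  expected-recovery cell and is excluded from the parameter count rather
  than fixed;
* a radio harvest rate for a season with no animals available
  (\(m_i = 0\)) is structurally fixed at 0 and excluded;
* the "no transmitter effect" constraint \(H_i = H_{ri}\) is index
  aliasing, not a penalty: radio cells carry `tag_type = "radio"`, so
  when `tag_type` is absent from the harvest structure both data streams
  point at the same free parameters.

Internally every recovery-cell probability is a pure product of
parameters and is stored as an integer exponent vector, so the
log-likelihood and its exact gradient are matrix products. This also
gives cheap likelihood refreshes when only the counts change between
simulation replicates.

## Estimation choices

* **Link.** All probabilities are estimated on the logit scale;
  parameters fixed at 0 or 1 bypass the link entirely (they are not free
  parameters).
* **Optimizer.** BFGS with analytic gradients, convergence tolerance
  1e-8 on the objective (relative 1e-10 in `optim()`), at most 500
  iterations. Starting values come from closed forms: interval MLEs for
  monthly survival, diagonal-cell moment estimates for harvest, first
  superdiagonal for annual survival, \(h/m\) for radio rates. The
  default `n_starts = 5` adds four deterministic jittered restarts
  (fixed internal seeds) and keeps the best optimum; simulation grids use
  a single informed start, which the restart-stability test shows reaches
  the same optimum to within 1e-4 log-likelihood units.
* **Infeasible corners.** Cell probabilities can momentarily sum past 1
  during a line search (e.g. \(H_1 + S_1 > 1\)); a smooth quadratic
  penalty keeps the objective finite there instead of returning
  \(-\infty\).
* **Standard errors.** Inverse observed information (Jacobian of the
  analytic gradient), delta-transformed to the probability scale.
  Estimates at 0/1 boundaries, and parameters carrying no information at
  the optimum (e.g. a month with no deaths, estimated at 1), are flagged
  and reported without SEs rather than with spuriously small ones.
  `cumulative_survival_se()` propagates the monthly variance–covariance
  into \(\mathrm{SE}(S_G)\) by the first-order delta method, written so a
  zero monthly estimate still yields a well-defined SE.
* **AICc.** \(\mathrm{AICc} = -2\ell + 2K + 2K(K+1)/(n-K-1)\). The
  effective \(n\) is taken as the total number of marked individuals:
  tagged releases plus known-fate entries, plus radio-harvest
  availability only when no known-fate stream is present (the same
  radio-marked animals usually appear in both). This is the dominant
  convention for recovery models but not the only defensible one, so
  `fit_joint_model(n_eff = )` lets the user override it and the value is
  recorded in every report. Ties in AICc ranking are broken by smaller
  \(K\), then input order; weights are the usual
  \(w_m = e^{-\Delta_m/2} / \sum e^{-\Delta/2}\).
* **Likelihood constants.** Binomial and multinomial coefficients are
  dropped everywhere, so log-likelihoods are comparable only between
  models fitted to the same data; AICc differences are unaffected.

## The simulation engine

`scenario()` fixes a three-year, one-age-class design with constant true
rates; the two shipped life histories are species A
(\(S_G = 0.90, H = 0.60, S = 0.30\): heavily harvested, short-lived) and
species B (\(S_G = 0.69, H = 0.10, S = 0.60\): light harvest, heavier
pre-season mortality). The allocation grid defaults to 0–200 radio
transmitters by 50–600 reward tags released *each year* (three annual
cohorts). `simulate_dataset()` draws each radio-marked animal through
\(G = 9\) monthly Bernoulli survival trials (no censoring) and each
tagged cohort from the recovery multinomial; radio-marked animals are
simulated only through the pre-season months, so in these scenarios the
transmitter data inform only tagging-to-harvest survival, never the
harvest rate itself.

`run_grid()` fits the standard Brownie model (survival fixed at 1,
\(K = 5\)) to 0-radio allocations and the joint model (year-specific
monthly survival, \(K = 32\)) otherwise, collecting year-specific harvest
estimates across replicates. Reported metrics per allocation-year:

* absolute bias (mean estimate minus truth) and relative bias,
* \(CV = 100\,\mathrm{SD}/\mathrm{mean}\) of the replicate estimates,
* \(CV(\mathrm{RMSE}) = 100\sqrt{\mathrm{mean}((\hat H - H_t)^2)}/H_t\),
  and its percentage-point difference from the 0-radio Brownie baseline
  at the same tag count (negative = joint worse).

Two reading choices deserve note because the source material for this
model family leaves them open. First, the CV is computed as SD over mean
of the replicate estimates; SD over truth and average-estimated-SE
conventions exist, which is why the package's own precision checks use
generous tolerances. Second, grid summaries average each allocation-year
cell over replicates first and then summarise (mean/min/max/SD) across
the allocation x year cells; this reading is recorded in the output
object.

Bias/precision checks in the test suite use 500 replicates per 0-radio
allocation and 200 per joint allocation over a 4 x 7 radio-by-tag
sub-grid; `scripts/acceptance.R` runs the full 7 x 7 joint grid at 200
replicates. Reproducibility is per-cell: every (allocation, replicate)
dataset derives its own child seed from the master seed by a counter, so
any single cell can be regenerated in isolation.

**What the generator does and does not emulate.** It matches the design
study's structure: annual cohorts, constant true rates, multinomial
recoveries consistent with the fitted cell probabilities (a chi-square
check in the tests), independent fates. It does not generate
heterogeneous individuals, tag loss, imperfect reporting, censoring, age
structure, or hunter behaviour; passing tests therefore demonstrate the
estimator's properties under its own assumptions, not robustness to
their violation.

## Case-study fixtures

`make_case_study_fixture()` builds fully synthetic datasets shaped like
the two motivating field designs, with the generating truth attached as
an attribute: a turkey-style design (3 years, January–March staggered
entries, adult/juvenile strata, reward bands on all birds, transmitters
on a subset, adult \(S_G \approx 0.45\)) and a deer-style design (3 years
x 4 management units x 2 ages, ear tags plus a radio-harvest stream,
monthly survival above 0.98, `hr_ratio` to inject a true transmitter
effect). These fixtures exercise the motivating model structures — the
turkey year-varying vs constant pair (\(K = 23/20\)) and the deer
candidate set (null \(K = 10\), age \(18\), year \(22\), tag type
\(14\)) — and parameter recovery at realistic sample sizes. They are
synthetic stand-ins: none of the original field data ship with the
package, so no field estimates are reproduction targets here. Deer cohorts keep their capture age class
throughout (no juvenile-to-adult transition), consistent with how the
candidate-set parameter counts are defined.

## Known limitations

* No live recaptures or resightings, no multi-state or covariate
  modelling, no reporting-rate (\(\lambda < 1\)) estimation, no
  profile-likelihood or Bayesian intervals, no random effects.
* Factor structures are full crossings; additive (main-effects) link
  structures are not available.
* The displayed likelihoods assume recoveries occur only in years with
  releases.
* Normal-theory intervals on the logit scale can be poor for parameters
  near boundaries with little data; boundary estimates are flagged
  instead of interval-reported.
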