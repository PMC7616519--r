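---
title: "Comparing heat-health associations across overlapping encounter datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing heat-health associations across overlapping encounter datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatcc)
```

## The problem

Claims databases from commercial insurers cover only a slice of a state's
population, and that slice differs from the state in age, sex, and
geography. Before using such a database to study how extreme heat affects
healthcare utilization, one wants to know whether the heat-health
associations it yields generalize: are they the same as those estimated
from a near-complete hospital discharge dataset covering the same state and
years? The two data sources describe overlapping people but cannot be
linked at the individual level, so the comparison has to work on aggregated
daily counts.

`heatcc` implements that comparison end to end: heatwave exposure
construction, claims-to-encounter aggregation, direct standardization,
space-time-stratified case-crossover estimation by conditional
quasi-Poisson regression, and a combined-dataset ratio-of-incidence-rate-
ratios (rIRR) estimator. A synthetic-data generator with known ground
truth makes every stage testable without access to restricted health data.

## Exposure model

A county's heatwave threshold is the year-round 97.5th percentile of its
daily maximum temperature over a multi-year baseline period. "Year-round"
matters: the percentile is taken over all calendar days, not only summer,
so the threshold sits near the top of the county's whole distribution. The
quantile uses the linear-interpolation convention (type 7, index
$h = 1 + (n-1)q/100$ on the sorted sample). The convention is recorded in
the output attributes because thresholds — and hence heatwave-day counts —
are sensitive to it, and different software defaults differ.

A heatwave is a maximal run of at least `min_run = 2` consecutive days with
daily maximum strictly above the threshold; every constituent day of a
qualifying spell is an exposed day (`hw_any`). "Exceeds" is strict: a day
exactly at the threshold is not an exceedance. Isolated exceedance days are
kept as the simpler sensitivity exposure (`exceed_simple`), and spell days
are additionally labeled first vs later (`hw_first`, `hw_later`) for
sensitivity analyses of within-spell timing. Gaps in a temperature series
break runs; no imputation is attempted.

## Outcome construction

Claim-level records are grouped into encounters by transitive chaining: a
claim joins the open encounter when it falls within one calendar day of
the previous claim for the same person, so a run of claims on consecutive
days collapses into a single encounter dated at the first claim. We read
the grouping rule this way (rather than anchoring a fixed window at the
first claim) because encounters are dated by first claim date, which makes
consecutive-day runs naturally collapse; the choice is flagged here because
claim-chaining conventions differ across studies. An encounter containing
any inpatient claim is classified inpatient — only all-ED encounters count
as ED — matching how discharge datasets record an ED visit that turns into
an admission. When claims within one encounter disagree on cause, the
earliest claim's cause wins, with alphabetical order as the tie-break; the
cause taxonomy itself is an abstract label set here, since diagnosis-code
mappings are site-specific.

Encounters are aggregated to daily counts keyed by (dataset, date, county,
age group, sex, cause, encounter type). The seven adult age bands are
18-24, 25-34, ..., 75+. Census tables in 5-year bands are adapted by
moving 40% of the 15-19 band (2 of 5 single years) into 18-24, either
deterministically or by a binomial draw.

## Person-time and standardization

Person-time at risk is stratum-by-day: for the insured dataset, each date
contributes that month's enrollee count in the stratum; for the reference
dataset, the annual census count. Incidence rates are reported per million
person-days.

Standardization re-weights insured counts to the reference composition
with year-specific weights

$$w(s, y) = \frac{P_{\mathrm{ref}}(s,y) / \sum_s P_{\mathrm{ref}}(s,y)}
                 {P_{\mathrm{ins}}(s,y) / \sum_s P_{\mathrm{ins}}(s,y)},$$

the ratio of within-year stratum shares. After re-weighting, insured
stratum shares equal reference shares exactly in every year (a tested
invariant, to 1e-9). Weights are year-specific rather than pooled because
enrollment composition drifts year on year. Strata with zero insured
population get weight zero with a warning; a year with zero insured total
is an error. The formula is recorded in the output metadata since
re-weighting conventions vary.

One presentational caveat: demographic comparison tables round shares for
display, and a ratio recomputed from rounded shares can differ in the last
digit from a ratio computed on full-precision shares (e.g. 11.3/17.3 is
0.65 from the printed values but may print as 0.66 when computed before
rounding). `demographic_ratio_table()` computes at full precision and
rounds only the final ratio; annual shares are averaged across years
before ratios are taken, which for slowly drifting compositions differs
negligibly from ratioing averaged counts.

## The case-crossover model

The design is a space-time-stratified case-crossover: each county-day is
compared only with the other days sharing its county, year, month, and
day-of-week (ISO convention, Monday = 1). Within such a stratum,
time-invariant and slowly varying confounders — county composition,
seasonality, weekly patterns — cancel by design. The daily count
$N_{t,s}$ follows a quasi-Poisson model

$$E(N_{t,s}) = \exp\{\beta_1 \, hw_{t,s} + \beta_2 \, RH_{t,s} +
\beta_3 \, h_t + \alpha_s\},$$

with heatwave day $hw$, same-day relative humidity $RH$ entered
untransformed on the 0-100 percent scale, holiday indicator $h$, and one
nuisance intercept $\alpha_s$ per stratum. Rather than estimating
thousands of $\alpha_s$, `fit_conditional_poisson()` conditions them out:
given the stratum total $n_s = \sum_t N_{t,s}$, the within-stratum counts
are multinomial with day probabilities
$\mathrm{softmax}(x_{t,s}'\beta)$, so the conditional log likelihood is

$$\ell(\beta) = \sum_s \Big[ \sum_t N_{ts} x_{ts}'\beta - n_s \log
\sum_t e^{x_{ts}'\beta} \Big].$$

This is exactly the profile likelihood of the stratum-intercept Poisson
model, so point estimates coincide with a stratum-dummy GLM fit (a tested
equivalence, at 1e-6) at a small fraction of the cost. Strata whose total
count is zero contribute nothing and are removed before fitting, with a
logged tally; days with zero events on no-event days still matter and are
retained as referent days.

Numerical choices: Newton-Raphson from $\beta = 0$ with step-halving;
within-stratum softmax computed max-shifted to avoid overflow;
convergence when the score drops below `1e-10` or the relative
log-likelihood change stays below `1e-10` for two consecutive iterations
(the doubled check buys one extra quadratic refinement, which matters when
asserting closed-form solutions to 1e-9); ill-conditioned information
matrices get a ridge jitter of 1e-10 with a warning. An exposure column
that is constant within every stratum is a hard non-identifiability error;
a control column constant within every stratum is absorbed by the
intercepts and is dropped with a warning, leaving the remaining estimates
unchanged (a tested invariance).

Overdispersion is handled quasi-likelihood style: the Pearson dispersion
$\hat\varphi = X^2 / (n_{\mathrm{obs}} - n_{\mathrm{strata}} - p)$ with
fitted means $\hat\mu_{ts} = n_s\,\mathrm{softmax}_s(X\hat\beta)$ scales
the covariance. The residual degrees of freedom deliberately count the
eliminated stratum intercepts as estimated parameters — this matches the
profile-likelihood equivalence and the stratum-dummy GLM convention, and
is stated explicitly because software differs on it. Non-integer outcomes
(standardized counts) pass through the quasi-score equations unchanged.
Confidence intervals are Wald, $\exp(\hat\beta \pm 1.96\,SE)$; no profile
intervals are computed.

The main analysis aggregates counts over age-sex within county-day,
because the stratification is by county, year, month, and weekday only;
keeping age-sex in the stratum key is available as `by_age_sex = TRUE` for
sensitivity analyses on widened age strata. RH enters same-day and
untransformed; no lag structure is modeled.

## Comparing the two datasets: the rIRR

Naive comparisons of the two estimated $\hat\beta_1$'s are flawed in both
directions. The independent-SE difference test assumes the two estimates
are uncorrelated, but both datasets see the same heatwaves and overlap in
population, so its size is wrong in a direction that depends on the sign
of the covariance. The CI-overlap rule (call them different only if the
95% CIs are disjoint) is conservative. Both are implemented as explicit
foils (`naive_independent_difference()`, `ci_overlap_rule()`), and
`run_comparison_experiment()` measures their type-I error, power, and
coverage against the combined estimator on replicated synthetic studies.

The combined estimator stacks both datasets, adds the dataset label to the
stratum key (so strata stay dataset-pure), and interacts a dataset dummy
$d_t$ (0 = reference, 1 = insured) with every covariate:

$$E(N_{t,s}) = \exp\{\beta_1 hw + \beta_2 RH + \beta_3 h +
\beta_4 [d_t \times hw] + \beta_5 [d_t \times RH] + \beta_6 [d_t \times h]
+ \alpha_s\}.$$

$d_t$ itself is omitted — it is constant within every stratum and would be
absorbed by $\alpha_s$. Then $\exp(\beta_4)$ is the ratio of the two
heatwave IRRs (rIRR), oriented so rIRR > 1 means a stronger association in
the insured dataset. Because the strata are disjoint across datasets and
the model fully interacted, the combined point estimates factorize exactly
into the two separate fits ($\beta_1 \leftrightarrow$ reference,
$\beta_1 + \beta_4 \leftrightarrow$ insured; tested to 1e-6) — but the
combined fit pools the Pearson dispersion across datasets, so its standard
errors are not simply the separate ones; all dispersion estimates are
reported side by side.

## What the synthetic generator emulates — and what it does not

The generator exists so that estimator properties can be verified against
known truth. Its defaults define the study conditions used throughout the
test suite, chosen once to be realistic for a warm-climate state:

* **Climate**: daily county tmax = seasonal sinusoid (amplitude 9 °C,
  peak mid-July) + AR(1) residual (lag-1 correlation 0.7, innovation SD
  2.5 °C), counties offset by N(0, 2 °C); relative humidity negatively
  correlated with the temperature anomaly (r = -0.4), clipped to
  [0, 100]%. This produces occasional multi-day heat spells; under the
  defaults roughly 4-7% of warm-season days are heatwave days, the order
  observed in temperate-state summers.
* **Populations**: log-normal county sizes around 200,000 adults, a fixed
  adult age pyramid, near 50/50 sex split, 0.4%/year growth. Insured
  coverage 3.4% of the reference by default — the order of a single
  commercial insurer's share of a large state — with 2% month-to-month
  enrollment jitter.
* **Counts**: stratum-day counts with mean person-days × baseline rate ×
  exp(linear predictor). The reference all-cause baseline is 8×10⁻⁴
  encounters/person-day (≈ 800 per million person-days, the order of
  all-cause ED rates in discharge data); the insured dataset uses 0.4× that
  baseline, reflecting lower observed utilization in claims. True
  heatwave IRRs default to 1.1 (reference) and 1.2 (insured); RH adds
  0.002 log-rate per percentage point and holidays 0.05.
* **Overdispersion**: 1.3 by default, implemented as a gamma-mixed Poisson
  whose gamma shape is $\mu/(\varphi-1)$, giving variance $\varphi\mu$ at
  every mean — exactly the quasi-Poisson variance function the model
  assumes, so the fitted dispersion estimates the generating $\varphi$.
  The value 1.3 is a design choice within the plausible range for daily
  encounter counts (dispersion in such analyses typically sits below 1.5).
* **Randomness**: one root seed; each component (climate, population,
  counts per dataset, each experiment replicate) derives an independent
  stream, so components can be regenerated independently and all outputs
  are byte-identical under a fixed seed.
* **Holidays**: eight fixed month-day dates per year as a synthetic
  default; real analyses should pass the jurisdiction's actual list.

The generator deliberately omits features of real data: no spatial
correlation between counties, no migration or mortality, no within-stratum
demographic drift beyond smooth growth, no diagnosis-code structure, no
reporting lags or data-quality artifacts, and the two datasets are
conditionally independent given the shared exposure series (real insured
encounters are a subset of the reference dataset's). Passing tests
therefore demonstrate that the estimators recover known effects under the
model's own assumptions — not that those assumptions hold in any
particular claims database. In particular, the naive-comparison
experiments understate the correlation between the two datasets'
estimates relative to a true subset relationship, which makes the
demonstrated size distortions conservative.

## Problem sizes used in the verification suite

The test suite exercises parameter recovery at 200 replicated studies of
20 counties × 2 warm seasons (bias of the exposure coefficient within
twice its Monte-Carlo standard error; rIRR CI coverage between 0.90 and
0.98) and null calibration at 500 replicates of 12 counties × 2 warm
seasons (rejection rate within [0.03, 0.08] at nominal 0.05). These sizes
give Monte-Carlo standard errors near 0.01 on rejection rates, small
enough to detect meaningful miscalibration while keeping the suite
runnable on a laptop.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_study(n_counties = 8, years = 2018:2019, seed = 7)
res <- fit_rirr(sim$strata_ref, sim$strata_ins)
res
#> rIRR (insured vs reference): 1.145  [0.992, 1.322]
#>   IRR reference: 1.093 [1.074, 1.112]   IRR insured: 1.252 [1.086, 1.443]
#>   dispersion: combined 1.311, reference 1.315, insured 1.308
```

The true IRRs behind this run are 1.1 and 1.2 (true rIRR 1.09): both fall
inside their intervals, and the fitted dispersions recover the generating
overdispersion of 1.3.

## Known limitations

* The standardization formula (ratio of within-year shares) is one of
  several defensible re-weighting conventions; it is recorded in output
  metadata and isolated behind `standardization_weights()` so an
  alternative can be swapped in.
* Wald intervals can undercover for very sparse outcomes (few strata with
  events); no small-sample exact conditional inference is provided.
* No distributed-lag or nonlinear temperature terms; the exposure is a
  binary spell indicator by design.
* The claims-chaining rule is transitive; studies that anchor a fixed
  window at the first claim will split long runs differently.
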