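---
title: "Partitioning fish size-structure variation between fishing and temperature"
author: "SizeVarPart authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning fish size-structure variation between fishing and temperature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SizeVarPart)
```

## The question and the response variable

An exploited fish stock's size structure — the distribution of individuals
over length classes — is shaped from two directions.  Size-selective
fishing removes large individuals and truncates the distribution from
above, within the year the fishing happens.  Temperature acts mostly from
below and with a delay: a warm or cold year changes recruitment success,
and that cohort only enters the surveyed size range one or more years
later.  The question this package answers per stock is: *how much of the
year-to-year variation in length composition is attributable to fishing,
how much to temperature, and how much cannot be separated between them?*

The response is the full annual length composition, not a univariate
summary.  Each survey year contributes a row of proportions over length
bins.  Proportions (rather than raw counts) remove survey-effort
artefacts: a year with twice the sampling should not look like a change in
size structure.  An optional Hellinger transform (square root of
proportions, `transform = "hellinger"`) is available for users who prefer
the composition-analysis convention that downweights dominant bins; the
default is plain proportions, and all shipped results use it.  Length bins
are half-open `[lower, upper)` intervals in centimetres, kept exactly as
each stock's survey defines them — the analysis is per-stock, so bins are
never harmonised across stocks.  Bins that are empty in every analysed
year carry no variance and are dropped before ordination.

## Redundancy analysis and the two-set partition

Redundancy analysis (RDA) is multivariate regression summarised by an
explained-variance fraction: with the response matrix and predictors
column-centred, `R²` is the Frobenius sum of squares of the projection of
`Y` onto the predictor space over the total centred sum of squares.
Because a one-predictor RDA is just a stack of simple regressions, the
implementation is checked in the test suite against a brute-force
per-column OLS oracle (to 1e-10) and against an independent
constrained-ordination program (`vegan`).

Raw `R²` grows mechanically with predictors relative to years, and stocks
here have as few as 9 survey years, so all reported fractions use
Ezekiel's adjustment `1 − (1 − R²)(n − 1)/(n − p − 1)`, which is unbiased
under random predictors and may legitimately go negative.  With `A_f`,
`A_t`, `A_ft` the adjusted R² of the fishing-only, temperature-only and
joint models, the partition is `a = A_ft − A_t` (pure fishing),
`c = A_ft − A_f` (pure temperature), `b = A_f + A_t − A_ft` (shared), and
the identity `a + b + c = A_ft` holds to machine precision.  The shared
fraction is the overlap that correlated forcings explain jointly — it is
not a statistical interaction term, cannot be tested, and can be negative
(suppressor configurations).  Report tables follow the field's convention
of printing fractions clamped at zero to three decimals
(`reportedFractions()`); machine-precision unclamped values stay in the
`PartitionResult` object and all totals use unclamped arithmetic.  A note
on linearity: the whole construction is a linear variance decomposition,
so genuinely nonlinear fishing–temperature interactions are outside its
reach, exactly as they are for linear SBI regressions.

Aliased predictors are handled the way ordination software conventionally
does: the effective predictor count is the rank of the (residualised)
predictor matrix, so two identical forcings collapse to one constraint and
the partition puts everything into the shared fraction; a constant forcing
constrains nothing (`R² = 0`) rather than erroring, which also gives the
lag-selection tie-break below a well-defined degenerate case.

## Significance testing

Each pure fraction is tested with the standard partial constrained
ordination permutation test: the observed statistic is the pseudo-F
`(SS_exp/p) / (SS_res/(n − p − q − 1))` of the focal forcing given the
other one; null replicates permute the rows of the residuals of the
reduced model (conditioning forcing only), are re-residualised, and the
p-value is `(#{F* ≥ F_obs} + 1)/(nPerm + 1)`.  Permuting
reduced-model residuals rather than raw rows is the choice with the best
type-I behaviour for partial tests in the ordination literature; the test
suite verifies an empirical type-I error within [0.03, 0.07] at α = 0.05
over 1000 null datasets.  1000 permutations is the conventional default;
every stochastic operation takes an explicit integer seed and is
deterministic given it.

## Temperature lags and model selection

Fishing is never lagged — it removes adults immediately.  Temperature is
offered at lags 0, 1 and 3 years for annually surveyed stocks; for stocks
surveyed every 2–3 years a 1-year lag is not resolvable, so the candidate
set is {0, 2, 3} (a configuration switch restricts it to {2, 3} for users
who want lag 0 excluded for multi-year surveys; the default keeps 0
because an instantaneous response is always a meaningful null).  As the
partition estimates no likelihood, the model with the largest total
adjusted R² (largest effect size) is selected; ties break toward the
smaller lag on parsimony grounds.  Permutation tests are run for the
selected model only.

One consequence, verified by simulation in the test suite: selecting the
best of three lags inflates the selected-lag p-value under the null
(measured ≈16% rejection at α = 0.05 over 100 null stocks).  This is a
property of any select-then-test procedure, not of the permutation test,
which holds its nominal level at a fixed lag.  The package therefore
measures the test's false-positive rate at lag 0 and reports selected-lag
p-values as the method defines them; users comparing many stocks should
keep this inflation in mind when counting "significant" stocks.

## Size-based indicators

For comparison with univariate practice, `computeSBITable()` produces per
year: the interpolated weighted 95th length percentile (L95), mean length,
Shannon diversity (nats), Pielou evenness, and moment skewness.  Choices
the field's literature leaves open, fixed here: bin midpoints represent
lengths in the moment-based indicators; L95 interpolates linearly inside
the bin where the cumulative proportion crosses 0.95 (returning the bin
edge or midpoint would make the indicator a step function of the data);
skewness uses the population-moment form with no small-sample correction;
Pielou's `S` is the number of bins occupied at the stock level, constant
across years, so evenness is comparable between years of the same stock.
A year with all mass in one bin has zero spread: H = 0 and skewness is
returned as missing with a warning.

Each indicator is regressed on `temperature + fishing +
temperature:fishing`.  Both predictors are z-scored before the product is
formed: the marginal p-values are unaffected, but the product term is not
scale-free, and standardising keeps it from being dominated by whichever
forcing happens to have larger units.  A constant indicator returns zero
slopes with p = 1 rather than an error, so degenerate simulated stocks do
not abort batch runs.

## The exploitation-rate conversion

Some assessment programs report exploitation rate μ (the fraction removed
per year) instead of instantaneous fishing mortality F.  Under a type II
fishery — fishing and natural mortality operating concurrently through the
year — `μ = F·A/Z` with `Z = F + M` and `A = 1 − e^{−Z}`.  The inversion
brackets F (doubling the upper bound until the root is enclosed) and
solves by Brent's method to 1e-10 on μ; the round trip is exact to 1e-8
over F ∈ [0, 5], M ∈ [0.05, 1].  The CV of the mortality-ratio series F/M
uses the sample (n − 1) standard deviation.  All rates are treated as
annual.

## The synthetic-stock generator

`simulateStock()` exists so that every pipeline stage — alignment,
partition, permutation tests, lag selection, SBIs, meta-analysis — can be
exercised and power-checked without any survey download.  It is an
age-structured operating model with exactly the two mechanisms the
analysis is designed to detect:

* **Fishing truncation.** Cohorts survive
  `N_{a+1,t+1} = N_{a,t} e^{−(M + s(L̄_a) F_t)}` with logistic
  selectivity-at-length `s`, so rising `F_t` steepens the loss of large
  fish.  The default trajectory ramps F from 0.1 to 0.8 yr⁻¹ over the
  series with small random-walk noise (reflected at zero) — an
  industrialisation-era contrast strong enough to be the documented power
  scenario.
* **Lagged temperature forcing.** Recruitment is lognormal,
  `R_t = R0 · exp(β_T (T_{t−ℓ} − T̄) − σ_R²/2 + η_t)`, with the −σ²/2
  correction keeping mean recruitment stationary when β_T = 0.
  Temperature follows an AR(1) with mean 8 °C, ρ = 0.5 and innovation sd
  0.6 °C, a temperate-shelf-like series.

Observation is a survey measuring `nSample` fish per year: the year's
length distribution is the normal mixture over ages (sd =
`cvLength`·mean length at age) weighted by survey-vulnerable abundance,
discretised into 2-cm bins and sampled multinomially, so composition rows
sum to `nSample` exactly.  Survey vulnerability reuses the fishery
selectivity by default — the simplest mechanism that makes fishing
truncation visible in the observed composition.  For lag-recovery
experiments the survey selectivity is set separately (length at 50%
selection of 8 cm), because recruitment pulses can only date a temperature
anomaly if young fish are visible to the survey.

Default parameters describe a moderately long-lived demersal stock:
35 survey years (the data series behind the embedded table run 9–43
years), L∞ = 60 cm, K = 0.25 yr⁻¹, a0 = −0.5 yr, 12% length-at-age CV,
M = 0.25 yr⁻¹, fishery selection at 35 cm, R0 = 10⁶, β_T = 0.25 per °C,
σ_R = 0.4, recruitment lag 1, 5000 fish measured per year.  The maximum
age tracked is where cumulative natural survival falls below 1% (capped
at 40).  What the generator does *not* emulate: density-dependent
recruitment, time-varying M or selectivity, discarding, ageing error, or
spatial structure.  Passing the power and false-positive checks on these
stocks therefore shows the engine detects the mechanisms it models at
realistic sample sizes — not that real survey series are free of the
confounders the generator omits.

Problem sizes used by the shipped checks, chosen to characterise the
engine at survey-realistic scales while keeping a full run in minutes:
RDA-oracle agreement on 200 random instances; permutation type-I error on
1000 null datasets of 30 years × 4 bins at 200 permutations; power and
false-positive rates on 100 simulated stocks each; lag recovery on 50
seeds per true lag.

## The embedded 28-stock table and cross-stock statistics

The published per-stock partition results for 28 West US, Alaska and
North Sea stocks are embedded as a plain-text fixture
(`table2Fixture()`): clamped three-decimal fractions, significance flags,
and the selected lag per stock.  The cross-stock summaries
(`partitionTableSummary()`) and the paired t-tests across stocks
reproduce the published headline numbers from it.  Two caveats are worth
stating plainly.  First, the paired comparisons are run one-sided
("fishing explains more"), which matches the directional phrasing and the
published p-values for the two fishing comparisons exactly; recomputed
two-sided values are simply twice as large.  Second, the printed table is
clamped at zero and rounded to three decimals, which destroys information
the original tests used: the published temperature-vs-interaction and
within-region p-values are not recoverable from the printed columns under
any standard test, and the package reports what the printed data actually
give.  The habitat column of the fixture is a package-supplied
classification from standard species ecology (the published table does
not print one); it exercises the habitat-grouped code paths and carries
no reproduction weight.

The covariate screen regresses each stock's fishing (or temperature)
fraction on one covariate at a time — growth rate K, L∞, age and length
at maturity, mean and CV of F/M, mean and CV of temperature — by OLS,
then refits with a habitat random intercept (`lme4`, REML, Satterthwaite
p-values via `lmerTest`); a singular fit or single-habitat table falls
back to OLS with a flag.  The per-stock covariate values behind the
published screen are not distributable, so the machinery is validated on
constructed covariate tables with known slopes instead.  No
multiple-testing correction is applied anywhere, matching the practice
the package mirrors.

The efficiency comparison pairs, per stock and effect, the partition
permutation p-value with the corresponding term's p-value from each of
the five SBI regressions; a success is a *strictly* smaller partition p
(ties are failures, the conservative rule), and the success probability
is tested against 0.5 with a one-sided exact binomial test.

## Degenerate inputs and numerical conventions

All-zero survey years are rejected at load; zero-total rows cannot be
normalised.  Proportion rows sum to 1 within 1e-12.  Alignment drops a
year only if fishing, temperature-at-lag or composition is missing, and
requires 8 aligned years by default (the shortest published series has
9 degrees of freedom).  Constant forcings degrade gracefully as described
above; constant responses return p = 1 rather than NaN.  The partition
identity is maintained to 1e-10; permutation p-values are never zero by
construction.  Seeds are plain integers; batch runs derive consecutive
seeds so stocks are independent but reproducible.

## Known limitations

Linear responses only, one temperature series per stock, no
effort-standardisation of the compositions (assessment-report length
frequencies are assumed usable as-is), no type I (pulse) fishery variant,
and the selected-lag p-value inflation discussed above.  The mixed-model
screen treats habitat as the only grouping; region–habitat crossed
structures are left to the user.
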