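# SizeVarPart

Quantifying how much of the year-to-year variation in an exploited fish
stock's **length composition** is explained by **fishing**, by
**temperature**, and by their shared component.

Size-selective fishing truncates the size structure of a stock by removing
large individuals; temperature perturbs it indirectly, mostly through
recruitment, and therefore with a lag.  Univariate size-based indicators
(SBIs) such as mean length or the 95th length percentile compress the whole
length-frequency distribution into one number per year and can miss much of
the signal.  `SizeVarPart` instead treats the full annual composition of
length classes as a multivariate response and partitions its temporal
variance between the two forcings, for fisheries scientists who want a
size-structure-based alternative (or complement) to SBI regressions.

## The method

For one stock, let `Y` be the `n × m` matrix of annual length-class
proportions (years × bins), `f` the annual fishing mortality (never lagged)
and `t` the annual temperature at a candidate lag of 0, 1 or 3 years
(0, 2 or 3 for stocks surveyed every 2–3 years).  Redundancy analysis (RDA)
gives the fraction of the total centred sum of squares of `Y` explained by
each predictor set, adjusted for sample size with Ezekiel's formula

    adjR²  =  1 − (1 − R²) (n − 1) / (n − p − 1).

With `A_f`, `A_t`, `A_ft` the adjusted R² of the fishing-only,
temperature-only and joint models, the two-set partition is

    pure fishing      a = A_ft − A_t
    pure temperature  c = A_ft − A_f
    shared            b = A_f + A_t − A_ft        (can be negative)
    residual          1 − A_ft

The lag is chosen by the largest `A_ft` (effect size; ties go to the
smaller lag), and the two pure fractions are tested by permuting the
residuals of the reduced model under a pseudo-F statistic (the shared
fraction is not testable).  Around this core the package provides:

* the five classical SBIs (L95, mean length, Shannon H, Pielou J,
  skewness) and their `SBI ~ temperature + fishing + temperature×fishing`
  regressions;
* exploitation-rate → fishing-mortality conversion for a type II fishery,
  `μ = F (1 − e^{−(F+M)}) / (F + M)`, inverted numerically;
* a seeded age-structured simulator (von Bertalanffy growth, logistic
  size selectivity, AR(1) temperature forcing lagged recruitment,
  multinomial survey sampling) so every stage is testable without survey
  data;
* cross-stock meta-analysis: paired effect comparisons, covariate
  regressions and habitat-random-intercept mixed models, and an
  exact-binomial comparison of partition p-values against SBI p-values.

## Worked example

```r
library(SizeVarPart)

cfg   <- SimConfig(nYears = 35L, seed = 42L)   # fishing ramp 0.1 -> 0.8
stock <- simulateStock(cfg)
res   <- runStockAnalysis(stock, nPerm = 999, seed = 1)
res$partition
#> PartitionResult (lag 0, 35 years):
#>   fishing     0.431  (p = 0.001)
#>   shared      0.003  (not testable)
#>   temperature 0.000  (p = 0.435)
#>   total adjR2 0.432
```

The ramp in fishing mortality explains 43% of the year-to-year variation
in this stock's size composition (permutation p = 0.001, the smallest
attainable with 999 permutations), while temperature — which here forces
recruitment only weakly — explains none; the lag-0 model won the
model selection.  The same run yields the per-year indicators:

```r
head(computeSBITable(composition(stock)), 3)
#>   year      L95 meanLength shannonH   pielouJ   skewness
#> 1 2000 59.35484    43.1172 2.998422 0.8128274 0.00421142
#> 2 2001 59.33871    43.0944 3.004429 0.8144557 0.05024780
#> 3 2002 59.33962    42.7076 3.022674 0.8194017 0.03994938
```

The package also embeds the published 28-stock partition table as a
fixture for the cross-stock statistics:

```r
tab <- table2Fixture()
unlist(partitionTableSummary(tab))
#>          meanFishingPct     nFishingSignificant nTemperatureSignificant
#>                10.88214                12.00000                 7.00000
#>        maxTotalAdjR2Pct
#>                44.00000
pairedEffectComparisons(tab, alternative = "greater")
#>   group                pair  n        t            p
#> 1   all fishing-temperature 28 2.166591 0.0196295625
#> 2   all      fishing-shared 28 3.989581 0.0002274669
#> 3   all  temperature-shared 28 2.158500 0.0199712505
```

Fishing explains on average 10.9% of size-structure variation across the
28 stocks — significantly more than temperature (p ≈ 0.020) and than the
shared component (p ≈ 0.0002) — and is significant in 12 of 28 stocks
against 7 for temperature; fishing plus temperature never explain more
than 44%.

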