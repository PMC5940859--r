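Package: SizeVarPart
Title: Variation Partitioning of Fish Stock Size Structure into Fishing
    and Temperature Effects
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how the year-to-year variation in the length
    composition of an exploited fish stock is explained by fishing
    mortality, temperature, and their shared component, using redundancy
    analysis (RDA) based variation partitioning with Ezekiel-adjusted
    R-squared, permutation significance tests, and temperature-lag model
    selection.  Provides univariate size-based indicators (L95, mean
    length, Shannon diversity, Pielou evenness, skewness) and their
    regressions on the same forcings, exploitation-rate to
    fishing-mortality conversion for a type II fishery, a seeded
    age-structured stock simulator with temperature-forced recruitment
    and size-selective harvest, and cross-stock meta-analysis tools
    (paired comparisons, covariate regressions, mixed models, and an
    exact-binomial p-value efficiency comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    lme4,
    lmerTest
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'accessors.R'
    'stock-data.R'
    'mortality.R'
    'rda.R'
    'varpart.R'
    'sbi.R'
    'meta.R'
    'fixtures.R'
    'synthetic.R'
    'pipeline.R'
    'utils.R'
    'SizeVarPart-package.R'
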