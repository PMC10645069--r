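Package: replistat
Title: Statistical Assessment of Replication Study Pairs
Version: 0.1.0
Authors@R: person("Replistat", "Maintainers", email = "maintainers@replistat.org", role = c("aut", "cre"))
Description: Tools for analysing collections of original/replication study
    pairs with heterogeneous reported statistics. Converts per-condition
    summaries, t and one-degree-of-freedom F statistics, 2x2 proportion
    tables and regression coefficients into a common effect-size currency
    (standardized mean differences, log odds ratios, native slopes with
    standard errors); computes replication-consistency metrics (95%
    prediction intervals, the p-original consistency statistic, and
    heterogeneity-adjusted consistency at a given tau); reproduces the
    descriptive layer (cohort summaries, unadjusted Pearson correlations
    with a subjective replication score, effect-size shift summaries); and
    fits regularized Bayesian regressions (cumulative-logit ordinal,
    logistic and linear models with horseshoe shrinkage priors and
    cohort-level random effects) via a built-in no-U-turn sampler. A
    synthetic-data generator with full ground truth (design-dependent true
    effects, publication selection of originals, between-implementation
    heterogeneity) supports end-to-end calibration and recovery testing,
    and a small pipeline runner orchestrates the stages reproducibly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
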