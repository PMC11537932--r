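Package: enviromet
Title: Envirotyping-Based Optimization of Multi-Environment Trial Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing the allocation of multi-environment plant
    breeding trials using environmental covariates. Builds stage-windowed
    weather and soil covariate matrices tuned to crop cardinal temperatures,
    selects yield-predictive covariates by recursive feature elimination with
    a random-forest learner, constructs trace-normalized enviromic
    relationship kernels, delimits mega-environments by k-means, fits
    two-stage linear mixed models (REML) with identity, kernel, or
    cluster-structured genotype-by-environment covariance, and evaluates
    trial-network reduction scenarios by Cullis heritability, cost, and
    heritability per dollar, including economically weighted allocation to
    target populations of environments. Includes a synthetic trial-network
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
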