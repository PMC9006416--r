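Package: ccrsim
Title: Covariate Constrained Randomisation and Monte Carlo Power for
    Cluster Randomised Trials
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to design and evaluate two-arm parallel cluster
    randomised trials with continuous outcomes and binary cluster-level
    covariates. Enumerates or samples the space of 1:1 allocations, scores
    covariate balance with the Raab-Butcher weighted squared-difference
    metric, forms best- or worst-balanced candidate sets and randomises
    within them. Simulates individual-level outcomes from a
    random-intercept linear model, analyses them by restricted maximum
    likelihood with Satterthwaite degrees of freedom, and estimates Monte
    Carlo power and type I error over factorial scenario grids, including
    common-random-number comparisons of candidate-set sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    parallel,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    jsonlite,
    optparse,
    withr
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
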