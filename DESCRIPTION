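Package: survbalance
Title: Selection of Compositional Microbiome Balances for Censored
    Time-to-Event Outcomes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies the log-ratio balance of two disjoint sets of taxa
    (the normalized log ratio of their geometric means of relative
    abundances) most associated with a right-censored survival outcome.
    Supports Cox proportional-hazards and Weibull accelerated failure time
    models fitted with the balance as a single feature plus optional
    covariates, greedy step-wise forward selection of the two taxon sets,
    and a community-level kernel association pre-test (Bray-Curtis and
    Jaccard kernels, permutation p-values, Cauchy-combination omnibus)
    that raises a caution flag when no global association is detected.
    Includes a Dirichlet-multinomial simulator of compositional counts
    with balance-driven survival times for validation, and a command-line
    pipeline producing JSON reports and quartile-stratified predicted
    survival curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    vegan,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
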