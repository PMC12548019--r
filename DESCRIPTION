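Package: pfcomb
Title: Combined P-Value Function Inference for Pivotal Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Evidence synthesis for pairs (or small sets) of clinical trials
    through combined p-value functions. Implements six p-value combination
    methods (the two-trials rule as a maximum/Wilkinson combiner, fixed-effect
    meta-analysis as weighted Stouffer, Tippett, Fisher, Pearson, and
    Edgington), inverts the combined p-value function into median estimates
    and confidence intervals that are compatible with the combined test
    decision at every level, decomposes two-trial medians into implicit
    per-trial weights, and provides analytic and seeded Monte Carlo operating
    characteristics (bias, standard error, coverage, asymptotic estimands).
    Ships the published summary statistics of the RESPIRE and ORBIT
    bronchiectasis trials as fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
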