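Package: readclock
Title: Targeted Epigenetic Age Prediction for Mice from Bisulfite
    Amplicons, Droplet Digital PCR and Single Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for targeted murine epigenetic clocks. Calls per-read
    binary CpG methylation from bisulfite amplicon sequencing reads,
    aggregates per-CpG DNA-methylation levels and single-read pattern
    statistics, quantifies percent methylation from droplet digital PCR
    counts by Poisson statistics, trains multivariable-linear and lasso
    age predictors, assigns an epigenetic age to each sequencing read from
    its binary methylation pattern by grid maximum likelihood, and
    simulates stochastic-aging mouse cohorts (bell-shaped CpG age
    association, strain acceleration) so the whole pipeline can be
    exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
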