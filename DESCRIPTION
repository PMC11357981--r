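Package: astrovar
Title: Differential Variability and Recovery Profiling for Longitudinal
    Multi-Omic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for small longitudinal multi-omic cohorts
    sampled before, during and after a perturbation such as short-duration
    spaceflight. Implements mean-abundance-standardized coefficient-of-variation
    profiling with a shuffled-label permutation test of between-phase
    variability shifts, phase-contrast differential testing with recovery
    profile analytics (shared DEG fractions, directionality reversal,
    uniqueness summaries), preranked gene-set enrichment and hypergeometric
    overrepresentation analysis, promoter-window accessibility-expression
    concordance, and a seeded synthetic cohort generator with configurable
    spike-in perturbations for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    DESeq2,
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
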