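Package: cagmosaic
Title: Somatic CAG-Repeat Mosaicism from Fragment-Analysis Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies somatic mosaicism of expanded CAG repeats in
    spinocerebellar ataxias (SCA1, SCA2, SCA3, SCA7) from capillary
    electrophoresis fragment-analysis peak tables: modal repeat calling,
    expansion index (EI) with stutter exclusion and relative-threshold
    filtering, and percent-mutant-allele profiles. Provides longitudinal
    cohort statistics (per-individual expansion rate, mixed-effects EI-age
    slopes per disease group with Tukey contrasts, residualized comparisons
    by disease status, severity correlations), relative qPCR expression by
    the 2^-ddCt method, and seeded synthetic generators for
    electropherogram traces, longitudinal cohorts, tissue panels and Ct
    tables that provide ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    car,
    emmeans,
    stats,
    utils,
    yaml
Suggests:
    pbkrtest,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
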