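Package: corestab
Title: Core Microbiota, Temporal Stability and Taxa-Function Robustness
    for Longitudinal Microbiome Cohorts
Version: 0.1.0
Authors@R:
    person("corestab", "developers", email = "corestab@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal gut-microbiome cohorts
    sampled across life stages (Infant, Adult, Elder). Computes
    prevalence-threshold core microbiotas at a relative-abundance
    detection limit, within-individual Jaccard similarity decay over
    time with 60-day binning, a Jaccard core index against fixed
    reference cores, per-individual Taylor's power-law stability
    parameters (fluctuation amplitude V and scaling index beta) with
    standardization to a reference group and confidence-region
    classification, and taxa-function robustness (attenuation and
    buffering) of genome-content projections under taxon-knockout
    perturbations standardized against shuffled-genome null models.
    Includes a seeded synthetic-cohort generator emulating the
    statistical structure these analyses assume, rank-based group
    comparisons with Benjamini-Hochberg adjustment, and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
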