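Package: metabomix
Title: Mixture-Deconvolution Metabolite Identification and Differential
    Abundance for Untargeted LC-MS
Version: 0.1.0
Authors@R:
    person("Metabomix", "Developers", email = "metabomix@example.org",
           role = c("aut", "cre"))
Description: Annotates untargeted LC-MS peak tables against a formula-mass
    compound database and scores each match with an empirical-Bayes posterior
    probability of true identification, obtained by deconvolving the
    best-match mass-error distribution into a true component and a false
    component learned from second-best database matches. Includes
    peak-table ingestion and filtering, geometric-mean collapsing of
    technical replicates, per-compound differential abundance with Storey
    q-values and fold-change thresholds, genus-level 16S relative-abundance
    comparisons with taxonomy-flow aggregation, and a seeded synthetic-data
    generator with ground truth for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
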