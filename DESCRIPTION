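Package: cosel
Title: Core Outcome Selection for Clinical Trials: Delphi Consensus, AGREE II
    Appraisal, Outcome Pooling and Bayesian Network Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for selecting a core outcome set for clinical trials,
    built around the workflow used to choose evaluation outcomes for
    herbal-injection trials in acute exacerbation of chronic obstructive
    pulmonary disease (AECOPD). Implements Delphi consensus-round scoring
    (importance bands, agreement coefficients, coefficient of variation,
    expert authority via judgement and familiarity coefficients, selection
    and exclusion rules with evidence-based overrides), AGREE II guideline
    appraisal (standardized domain scores, intra-class correlation,
    recommendation grading), outcome-frequency pooling across randomized
    trials with a reporting-frequency filter and multi-source candidate
    merging, and a Bayesian random-effects consistency network
    meta-analysis with Gelman-Rubin convergence diagnostics, SUCRA
    ranking, and a Bucher direct-versus-indirect consistency check.
    A seeded synthetic-data generator produces expert panels, appraiser
    matrices, trial extraction records and trial networks so the full
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    metafor,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
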