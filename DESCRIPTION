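Package: qdspr
Title: Quantitative Detergent Solubility Profiling and Injury Time-Course
    Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical pipeline for label-free proteomics of tissue injury
    and repair: quantitative detergent solubility profiling (QDSP) with
    two-way interaction ANOVA on per-condition normalized solubility
    profiles, ratiometric time-course analysis with left-censored
    (downshifted-normal) imputation, protein-abundance versus lung-compliance
    regression, SAM-style bronchoalveolar-lavage-fluid (BALF) compartment
    enrichment scoring, Fisher and rank-based (1D/2D) annotation enrichment,
    and a synthetic-data generator with known ground truth that emulates the
    bleomycin lung-injury study designs for end-to-end validation.
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
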