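Package: symptomics
Title: Symptom Co-Occurrence Screening from Free-Text Patient Narratives
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for symptom-level ("symptomic") analysis of free-text
    patient narratives. Converts narratives into a cleaned binary patient by
    symptom matrix via a user-supplied symptom lexicon, then screens every
    symptom against a chosen index symptom (for example auditory
    hallucination) using phi correlations, Fisher-z confidence intervals,
    t-based p-values, post-hoc power, and Cohen effect-size bands, and scans
    for symptoms statistically independent of the index symptom. Includes a
    latent-threshold (Gaussian copula) generator of synthetic narrative
    corpora with known marginal prevalences and pairwise phi targets, so the
    whole pipeline is testable end to end without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: graphics, stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
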