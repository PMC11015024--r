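Package: shiftability
Title: Anti-PD-1 Response Signatures and Perturbation Shift-Ability Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds anti-PD-1 resistance (R) and sensitivity (S)
    gene-expression signatures from paired pre/on-treatment tumour
    transcriptomes by bootstrapped differential-expression feature
    selection with stratified cross-validation, scores perturbation
    transcriptomes (shRNA and compound, Connectivity-Map level-5 style
    z-score profiles) for their ability to shift tumours from an
    anti-PD-1-resistant to a -sensitive expression state using a
    from-scratch pre-ranked gene-set enrichment statistic, and clusters
    shifting compounds into mechanism groups from consensus
    expression-change signatures.  Includes single-sample enrichment
    scoring, GCT/GMT readers and writers, and synthetic-data generators
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), fgsea, mclust, pROC, jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
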