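Package: episcreen
Title: Episignature Discovery and Calibrated Classification for DNA Methylation Disorders
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives disorder-specific DNA methylation episignatures from
    reference case/control cohorts of array beta values, trains one-vs-rest
    linear support-vector classifiers with Platt-calibrated methylation
    variant pathogenicity (MVP) scores, and combines scores with
    hierarchical-clustering/MDS evidence and screening of imprinted and
    repeat-expansion loci into positive/negative/inconclusive reports.
    Includes a synthetic-cohort simulator with known ground truth (bimodal
    beta baselines, planted probe shifts, imprinted DMRs, mosaic mixtures,
    technical replicates) and a versioned on-disk knowledge database of
    signatures and trained classifiers.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    e1071,
    S4Vectors,
    SummarizedExperiment
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
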