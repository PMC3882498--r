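Package: snppanel
Title: Case-Control Association, Genetic Risk Scores and ROC Evaluation for SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A staged analysis pipeline for case-control studies of candidate
    SNP risk panels: genotype and sample quality control by call rate and
    monomorphism, per-SNP allelic association (Fisher exact tests, Woolf
    odds-ratio confidence intervals, dosage logistic regression),
    false-discovery-rate control (Benjamini-Hochberg and Storey-Tibshirani
    smoothed q-values), three genetic risk score models (allele count,
    log-odds-weighted, and relative population risk under Hardy-Weinberg
    genotype frequencies), ROC/AUC evaluation with DeLong paired comparisons
    and combination with a serum biomarker, two-proportion power and sample
    size calculation, and crude plus confounder-adjusted epidemiological
    regression including case-only multinomial models. A synthetic cohort
    generator with known genotype, biomarker and covariate effects makes
    every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
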