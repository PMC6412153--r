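Package: dimorphDE
Title: Sex-Dimorphic Differential Expression in Bulk Transcriptomes via
    Two-Level Quantile Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for discovering sex-differentially expressed genes in
    bulk tissue TPM (transcripts-per-million) cohorts such as GTEx peripheral
    nerve. Provides coding-gene TPM renormalization, clinical-metadata cohort
    assignment with exclusion rules, normalized Shannon-entropy gene filtering,
    a two-level quantile Wilcoxon rank-sum differential-expression test
    (median and conditional upper-quartile) with independent Benjamini-Hochberg
    false-discovery control at each level, strictly standardized mean
    difference (SSMD) effect sizes, PCA-based sample outlier screening,
    age-expression correlation analysis, gene-list annotation, and a
    ground-truth synthetic cohort generator for validating every stage without
    access to controlled donor data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
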