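Package: ptcmeta
Title: Two-Cohort Transcriptomic Analysis of Metastatic Papillary Thyroid Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested reimplementation of a discovery/validation transcriptomic
    workflow comparing primary papillary thyroid carcinoma tumors with (M1) and
    without (M0) distant metastases. Provides batch-aware per-gene differential
    expression with optional empirical-Bayes variance moderation, Bonferroni
    validation of a preselected gene panel, a Monte-Carlo random-panel null with
    an exact hypergeometric counterpart, pre-ranked gene set enrichment analysis
    (enrichment score, NES, gene-set permutation p-values, redundancy pruning)
    with cross-cohort concordance testing, qPCR relative quantification (Pfaffl
    efficiency correction, geNorm-style reference stability), clinical cohort
    summaries, and a synthetic-data generator emulating the study's two-cohort,
    two-batch structure so that every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea
Config/testthat/edition: 3
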