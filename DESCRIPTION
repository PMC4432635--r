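Package: exertome
Title: Repeated-Measures Analysis of Exercise Time-Course Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for subject-paired, multi-group expression
    time courses of the kind produced by human exercise intervention
    studies (baseline biopsy plus post-exercise recovery samples on
    expression arrays). Normalizes each sample to its subject's own
    baseline on the log2 scale, fits a per-transcript repeated-measures
    two-way ANOVA (time, group, time x group) with a subject random
    intercept estimated by REML, tests named cell-mean contrasts,
    applies Benjamini-Hochberg false-discovery-rate control per
    statistical family, and classifies transcripts as changed versus
    baseline, group-specific, exercise-general (independent or dependent
    of exercise type) or time-regulated under explicit rule sets. Also
    provides a planted-effect simulator for the paired three-group
    design, per-gene geometric-mean summaries with back-transformed
    standard errors, a gene-symbol query layer and deterministic
    spreadsheet-style TSV export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr,
    jsonlite
Config/testthat/edition: 3
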