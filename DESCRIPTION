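Package: angiomir
Title: Integrative miRNA Screening for Regulators of Tumour Angiogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative screen for microRNAs that regulate tumour
    angiogenesis, built around a per-sample pro-angiogenic signature score
    (mean of +/-1 above-median indicators over a gene panel), a median-decrease
    differential filter between high and low microvessel-density tumours,
    Spearman association layers (signature score, individual genes, methylation
    beta values, copy number), an optimal-percentile Kaplan-Meier cutpoint scan
    with log-rank testing and a permutation-adjusted minimum p-value, a
    transcription-factor/target intersection cascade, and a random-walk network
    relevance scorer. A seeded synthetic multi-omic cohort generator emulates
    the statistical structure the screen assumes (latent angiogenic activity
    driving gene expression, vessel counts and hazard), so every stage is
    testable end to end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    limma,
    igraph,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
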