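Package: cnitpipe
Title: Integrative Transcriptomic Profiling of Calcineurin-Inhibitor
    Nephrotoxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for marker discovery in
    calcineurin-inhibitor nephrotoxicity (CNIT) of kidney allografts from
    paired gene-expression and miRNA microarray profiles. Provides
    hybridization quality control (percent-present detection calls and
    GAPDH 3':5' degradation ratios), quantile normalization,
    dual-threshold probeset-level differential expression with
    Benjamini-Hochberg FDR control, three-contrast marker-specificity set
    algebra against acute rejection and interstitial fibrosis / tubular
    atrophy controls, directionality-constrained miRNA-mRNA target
    integration, Fisher-exact gene-set and upstream-regulator enrichment
    with activation z-scores, supervised hierarchical clustering, and qPCR
    delta-Ct group comparison. Seeded synthetic cohort generators emulate
    the study design so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    limma,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
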