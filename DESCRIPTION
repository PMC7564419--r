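Package: osfunnel
Title: Integrative CNV-Expression-Survival Prognostic Funnel and Drug
    Combination Scoring for Osteosarcoma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying prognostic copy-number signatures in
    cancer cohorts by integrating marker-level copy-number segmentation and
    three-state calling, per-gene Cox proportional-hazards screening of
    expression and copy-number state against overall survival, direction
    -consistent cross-cohort replication with an empirical overlap false
    discovery rate, chromosome-level enrichment of survival-associated
    copy-number genes (odds ratios from 2x2 tables with one-sided
    chi-square tests), and a four-criterion candidate prioritization
    funnel. Also implements in-vitro drug-combination scoring: median
    -effect (Chou-Talalay) IC50 fitting, combination indices, and Bliss
    independence deltas with additivity/synergy classification bands. A
    synthetic-cohort module generates survival cohorts, marker tracks,
    normal-tissue panels, and checkerboard dose-response matrices with
    known planted structure so that every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
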