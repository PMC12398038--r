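Package: stemscore
Title: Tumor Stemness Scoring by Single-Sample Gene-Set Enrichment and
    Signature Distillation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and applies transcriptomic stemness scores. Computes
    single-sample gene-set enrichment (ssGSEA) running-sum scores, distills a
    candidate gene-set collection into a consensus stemness signature via a
    discrimination (ROC-AUC) filter on labeled stem versus somatic profiles, a
    stability (coefficient-of-variation) filter on a cell-line panel, and
    consensus gene membership; applies the signature to tumor cohorts with
    high/low dichotomization, diagnostic ROC, Kaplan-Meier/log-rank and Cox
    proportional-hazards analyses; and computes 2x2 marker-by-clinicopathology
    chi-square associations. Includes a synthetic-data module that generates
    labeled stem/somatic panels, cell-line panels and survival cohorts with
    planted signal so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
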