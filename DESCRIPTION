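Package: metaboline
Title: QC, Pathway Activity and Association Analysis for Cell-Line Metabolomics
Version: 0.1.0
Authors@R:
    person("Metaboline", "Developers", email = "maintainer@metaboline.dev",
           role = c("aut", "cre"))
Description: A tested pipeline for replicate-structured untargeted metabolomics
    of cell-line panels. Provides replicate-ROC quality metrics, per-ion Lowess
    injection-order and confluency correction, ANOVA-driven batch/plate feature
    filtering tuned by reproducibility AUC, rank-based pathway activity scoring
    with minimum-hypergeometric calibration, tissue-controlled mutation to
    metabolite association T-statistics, score and drug-sensitivity pathway
    enrichment with synergy overlays, gene-metabolite correlation networks,
    mutation-subtype analysis with Fisher tests and pathway similarity trees,
    permutation statistics, and a fully seeded synthetic-study generator with a
    machine-readable ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
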