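Package: protlayers
Title: Multi-Layer Proteome Integration for Stage-Resolved Cancer Secretome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates plasma, tissue, and cell-line secretome proteomes to
    find proteins whose secretion tracks tumour progression. Provides
    stage-profile z-scoring and threshold-cut hierarchical clustering,
    forward/reverse SILAC ratio orientation and differential-secretion
    calling, Fisher exact cross-layer association with enrichment factors,
    annotation enrichment and two-group permutation GSEA, single-sample GSEA
    transcription-factor regulon activity, and kinase-substrate enrichment
    (KSEA) z-scores. A synthetic-data generator with known ground truth
    drives recovery tests for every stage, and a published 16-protein
    plasma/secretome table ships as a packaged verification fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    fgsea
Config/testthat/edition: 3
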