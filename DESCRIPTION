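Package: neurointeract
Title: Interactor Calling and Candidate-Gene Prioritization for Bait AP-MS
    in Neural Stem Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls candidate protein interactors from affinity-purification
    mass-spectrometry (AP-MS) spectral counts using control-condition PSM
    bounds and NSAF (normalized spectral abundance factor) enrichment ratios,
    classifies dual-antibody support, correlates partner expression with the
    bait across brain development, scores phenotype-term overlap between the
    bait syndrome and partner-linked diseases, flags neurodevelopmental
    candidate genes by loss-of-function intolerance and co-expression, and
    summarizes differential-expression tables and gene-set directionality.
    Ships the published DYRK1A partner table for human neural stem cells and
    synthetic-data generators with ground-truth labels for every input.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    fgsea,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, GeneExpression, Network
RoxygenNote: 7.3.3
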