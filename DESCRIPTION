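Package: tritime
Title: Tensor-Based Longitudinal Multi-Omics Case-Control Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for matched case-control multi-omics studies
    sampled at several timepoints before a clinical event. Measurements are
    binned into three-way arrays (subjects x features x timepoints), missing
    cells are imputed with an iterative Tucker3 model, and case-control sets
    are within-normalized. Classification uses N-way partial least squares
    discriminant analysis (NPLS-DA) with variable-importance-for-projection
    (VIP) feature selection, permutation-based validation, and per-timepoint
    linear discriminant validation on held-out subjects. Selected signatures
    are analyzed through time-window partial-correlation networks with
    elastic-net stability selection, and through gene-set and
    metabolite-class enrichment with Fisher's-method p-value combination.
    Includes a synthetic-cohort generator with planted signal for
    benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    glmnet,
    igraph,
    jsonlite,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
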