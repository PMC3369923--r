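Package: omicforge
Title: Linear Steady-State Multi-Omics Models and In Silico Genome Redesign
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Infers sparse three-layer linear steady-state models linking gene
    expression, metabolite levels and agronomic traits across panels of
    recombinant inbred lines, using mutual-information screening (CLR z-scores),
    LASSO support selection and least-squares refitting. Fitted model stacks
    support in silico gene knockout and over-expression by clamping expression
    at its observed range limits, exhaustive single and pairwise perturbation
    scans, and greedy multi-gene optimization of weighted metabolite and trait
    objectives. Includes a synthetic panel generator with planted ground truth,
    bootstrap positive-predictive-value and false-positive-rate significance,
    perturbation-signature metabolite correlations with dendrograms and Mantel
    tests, and overlap enrichment against engineered validation lines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    glmnet,
    jsonlite,
    ape,
    vegan,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
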