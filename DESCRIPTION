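Package: mhonet
Title: Co-Expression Network Signatures of Metabolically Healthy Obesity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Whole-blood transcriptomic analysis of metabolically healthy
    versus metabolically abnormal obesity. Implements weighted gene
    co-expression network construction with scale-free soft thresholding,
    topological-overlap clustering and module-eigengene/trait association
    under a dual significance rule; negative-binomial likelihood-ratio
    differential expression with two-level dispersion shrinkage, deviance
    goodness-of-fit screening and power simulation; balanced random-forest
    classification with permutation variable importance, data-driven
    variable selection and metabolic driver ranking; the clinical
    MHO/MAO phenotype definitions; and a seeded synthetic-cohort
    generator with planted co-expression modules for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
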