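Package: mdnmf
Title: Microbe-Disease Co-Module Discovery by Graph-Regularized
    Nonnegative Matrix Tri-Factorization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies microbe modules, disease modules and their paired
    co-modules from a binary microbe-disease association matrix by jointly
    tri-factorizing the association matrix together with Gaussian
    interaction-profile kernel similarity matrices, under graph Laplacian
    penalties built from microbial phylogenetic distances and symptom-based
    disease similarities. Includes multiplicative-update solvers with a
    multi-restart protocol, soft-clustering module extraction with a
    mean-plus-t-standard-deviations threshold, inter-module link scoring
    from the central factor, local hypergeometric taxon-set enrichment with
    Benjamini-Hochberg control, an enrichment-index evaluation, and a
    planted-block synthetic data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
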