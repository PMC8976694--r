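Package: orchardgx
Title: Quantitative Genetics for Multi-Environment Clonal Crop Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for clonally replicated, multi-environment
    crop trials: spatial adjustment of tree-level phenotypes, clonal-value
    (BLUP) estimation and clonal-mean heritability, multi-locus genome-wide
    association scans with locus cataloguing and allele-frequency dynamics,
    main-effect and multi-environment (genotype-by-environment) genomic
    prediction with Gibbs samplers (G-BLUP, BayesC-pi, multi-kernel RKHS,
    random forest, multivariate and factor-analytic models), cross-validation
    under two masking scenarios, genomic heritability, and phenotypic
    variance decomposition with trait clustering. A synthetic-trial generator
    with known ground truth makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    mgcv,
    ranger,
    Rcpp,
    jsonlite,
    methods,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
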