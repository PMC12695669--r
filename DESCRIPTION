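Package: margepi
Title: Marginal Epistasis Variance Components via Randomized Method of Moments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Jointly estimates genome-wide additive and target-SNP marginal
    epistasis variance components from biobank-style genotype data using a
    randomized Method-of-Moments estimator with Hutchinson stochastic trace
    sketching. Includes streaming PLINK 1 genotype input with quality control,
    phenotype normalization and covariate handling, LD-block-aware
    construction of the gene-gene interaction component, GWAS target selection
    with LD pruning, pairwise interaction tests, genomic-inflation
    diagnostics, and a synthetic-data module that reproduces the simulation
    architectures used to validate the estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
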