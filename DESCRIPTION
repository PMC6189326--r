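Package: semgwas
Title: Structural Equation Model GWAS with Phenotypic Causal Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-trait genome-wide association analysis with mixed-effects
    structural equation models. Infers a causal network among phenotypes from
    the posterior distribution of residual partial correlations (Gibbs
    sampling of a multi-trait animal model, highest-posterior-density
    decisions, inductive-causation search), fits a recursive structural
    equation mixed model given the network, scans SNPs holding variance
    components fixed, and decomposes each SNP effect into direct, per-path
    indirect, and total components via path analysis. Includes genotype and
    phenotype quality control, VanRaden genomic and pedigree numerator
    relationship matrices, and a synthetic-data generator with recorded
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
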