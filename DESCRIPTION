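Package: germtherm
Title: Genomic Analysis of Germination Response to Elevated Temperature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantitative-genetic analysis of seed
    germination under contrasting temperatures in structured diversity
    panels. Provides variant-level filtering of multi-sample VCFs (biallelic,
    indel proximity, depth percentile, mapping quality and allele-depth rules,
    plus windowed LD pruning), a GCTA-style genomic relationship matrix with
    classical multidimensional scaling of its dissimilarity transform, an
    EM-REML mixed-model engine (one average-information step for standard
    errors) returning gBLUPs, variance components and heritability, a
    GRAMMAR-style two-stage treatment of binary germination via latent-scale
    GLM residuals, and downstream cross-temperature, latitude and emergence
    regressions quantifying heat tolerance. A synthetic-cohort generator
    emulates structured genotypes and censored germination phenotypes so
    every stage is verifiable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
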