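Package: spgwas
Title: Sparse Genotype Storage and Fast Per-Variant Regression for
    Biobank-Scale Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rare-variant-optimized binary genotype container and a set of
    per-variant regression engines that compute directly on sparse genotype
    difflists. Variants are stored either as fixed-width 2-bit arrays or as
    sparse lists of (sample index, genotype) pairs, whichever is smaller, so
    that a singleton among hundreds of thousands of samples costs a few bytes
    rather than a fixed fraction of the cohort size. Association testing
    exploits the same sparsity: a Schur-complement block inverse completes the
    precomputed covariate Gram matrix per variant in O(p(k+p)) operations, a
    residualized two-parameter path downdates precomputed sums at missing
    genotypes, case-control testing uses logistic regression with a Firth
    fallback and an accelerated covariate-offset mode, and correlated
    phenotype panels can be rank-reduced by SVD before scanning. A seeded
    simulator of biobank-like exome panels (heavy rare-variant tail; age, sex
    and principal-component covariates; quantitative and binary phenotypes
    with known effects) supports calibration and power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
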