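Package: mpgei
Title: Kernel-Based Gene-Environment Interaction Tests for Rare Variants
    with Multiple Quantitative Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Region-based variance-component score tests for gene-environment
    interaction (GEI) effects of rare variants on one or several correlated
    quantitative phenotypes.  Four phenotype-space kernels (homogeneous,
    heterogeneous, projection and linear) model the correlation among a
    variant's interaction effects across phenotypes; tail probabilities of the
    resulting mixture-of-chi-square null distributions are computed with
    Kuonen's saddlepoint approximation backed by a moment-matching fallback.
    Includes readers for VCF genotypes and tabular phenotype data, a simulation
    engine for rare-variant genotypes and correlated phenotypes, and drivers
    for type-I-error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    vcfR
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
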