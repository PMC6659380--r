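Package: maternalmr
Title: Partitioning Maternal and Offspring Genetic Effects for
    Mendelian Randomization of Maternal Exposures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates maternal and offspring (fetal) genetic effects on
    offspring phenotypes from genotyped women reporting their own and/or
    their first offspring's phenotype, using a structural equation model
    with latent relative genotypes fitted by full-information maximum
    likelihood, or from pairs of unconditional GWAS summary statistics
    with sampling overlap estimated by cross-trait LD score regression.
    Partitioned maternal effects feed a two-sample Mendelian
    randomization toolkit (Wald ratios, random-effects IVW, MR-Egger,
    weighted median) for estimating causal effects of maternal exposures
    on offspring outcomes. Includes an asymptotic power calculator for
    alternative study designs and a Mendelian three-generation family
    simulator used throughout the test suite.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
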