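Package: cardioburden
Title: Rare-Variant Carrier Burden, Segregation Filtering, Survival and
    Matched-Pair Expression Analysis for Congenital Heart Disease Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for family- and cohort-based analysis of rare,
    damaging variants in a candidate cardiac gene. Implements pedigree
    segregation filtering of genome-wide variants down to candidate genes,
    protein-domain annotation and rare/damaging classification from
    PolyPhen-2 and SIFT scores, a carrier-collapsing case-control burden
    test built on a from-scratch two-sided Fisher exact test, Kaplan-Meier
    estimation with the Gehan-Breslow (generalized Wilcoxon) two-group
    test implemented from its defining formulas, matched-pair
    transcriptome fold-change analysis with TPM normalization, and a
    pair-blocked linear model for Western blot densitometry. A synthetic
    data generator reproduces the statistical structure of each input so
    every stage is testable without access to protected patient data.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
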