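Package: modyburden
Title: Gene-Level Burden Analysis of Ultra-Rare Loss-of-Function Variants
    in MODY Genes Stratified by Nonsense-Mediated Decay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gene-level carrier burden analysis of ultra-rare
    loss-of-function variants in maturity-onset diabetes of the young (MODY)
    genes, stratified by predicted nonsense-mediated decay (NMD) status.
    Provides transcript-model coordinate mapping, consequence and truncated
    protein prediction (HGVS fsTer notation), the 50-bp NMD rule, ultra-rare
    frequency filtering and carrier collapsing, exact 2x2 inference
    (conditional-MLE odds ratio, exact confidence intervals, Fisher test,
    Zelen homogeneity), co-segregation LOD scoring, simulation-based power
    analysis, a proinsulin cysteine-pairing model of truncation severity,
    and seeded synthetic-data generators with truth ledgers for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    bio3d,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
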