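Package: rvpanel
Title: Rare-Variant Prioritisation and Burden Analysis for Targeted Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for targeted gene-panel studies of rare disease
    cohorts: sample-level coverage quality control, population-frequency and
    deleteriousness hard filtering of annotated variant calls, research-variant
    prioritisation with a three-criterion predictor vote, gene intolerance
    classification from five constraint metrics (DOMINO, haploinsufficiency
    percentile, RVIS percentile, pLI, missense Z), trio-based inheritance and
    compound-heterozygote calling, diagnostic-yield summaries, and two
    gene-level burden statistics (exact binomial carrier-burden test with
    Bonferroni correction across panel genes, and an exact two-tailed binomial
    overabundance test against matched controls). Includes a seeded synthetic
    cohort generator so every stage is testable without external data, and
    packaged report tables from a 112-gene cerebral-palsy panel study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    vcfR,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
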