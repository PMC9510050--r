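Package: dnmtrio
Title: De Novo Mutation Discovery and Characterization in Multiplex-Family Trios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy toolkit for discovering and characterizing germline de novo
    mutations (DNMs) in whole-genome-sequenced parent-offspring trios from
    multiplex families. Implements three-caller consensus filtering with
    single-tool rescue, population-frequency and sibling-sharing filters,
    effective-genome-coverage mutation rates, read-backed parent-of-origin
    phasing, strand-collapsed substitution spectra and 96-trinucleotide
    signatures, CpG-methylation enrichment tests, KING-style kinship and
    consanguinity-confounder analysis, and parental-age regressions including
    identity-link Poisson models with per-family effects. Ships a fully
    synthetic multiplex-family cohort generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    tidyr,
    tibble,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    vcfR,
    withr
Config/testthat/edition: 3
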