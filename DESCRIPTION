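Package: mendelrisk
Title: Multi-Gene, Multi-Cancer Mendelian Risk Prediction from Family History
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A Mendelian risk engine for cancer genetic counseling. Given a
    family's cancer history as a pedigree and a database of age-specific
    cancer penetrances and pathogenic-variant allele frequencies, it computes
    each counselee's posterior probability of carrying germline mutations in
    any combination of susceptibility genes, and projects their future cancer
    risks. The multi-locus genotype space is truncated with the
    peeling-paring approximation and posteriors are computed by
    Elston-Stewart pedigree peeling; missing current and diagnosis ages are
    handled by multiple imputation. Includes pedigree validation and repair
    (heredity harmonization, loop detection, pseudo-parent insertion), a
    forward pedigree simulator with known genotype truth, and an exact
    brute-force posterior for verification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
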