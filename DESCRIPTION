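Package: rflpid
Title: PCR-RFLP Profile Databases and Fungal Species Identification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for identification of fungal species by PCR-RFLP of the
    ITS1-5.8S-ITS2 barcode region. Extracts primer-delimited amplicons from
    genome sequences with mismatch-tolerant degenerate primer matching,
    simulates restriction digestion with IUPAC-ambiguous recognition sites,
    builds and serializes species-by-enzyme fragment-profile databases,
    ranks enzymes and enzyme combinations by discriminative power,
    calibrates gel fragment-size measurement-error models (ordinary least
    squares and a heteroscedastic AR(1) generalized least squares model),
    identifies species from measured profiles by progressive selection with
    permissive size ranges, and searches pruned enzyme-combination spaces
    for precise identification panels. Includes a synthetic-data generator
    with exact planted truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    nlme,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
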