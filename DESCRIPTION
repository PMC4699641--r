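Package: dsquad
Title: Prediction of Intrastrand and Interstrand G-Quadruplex Forming Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans nucleotide sequences for putative G-quadruplex forming
    sequences (PQS) whose four guanine tracts come from one strand or are
    distributed between both strands of duplex DNA. Implements the ten
    tract-order topology classes of double-strand-derived PQS (DS-PQS),
    Perl-compatible global regular-expression matching with backreferences,
    merging of overlapping predictions into unique sites, per-chromosome
    summary statistics, and binomial enrichment analysis of PQS against
    functional interval sets such as ChIP-seq peaks and promoters. Includes
    a synthetic-sequence generator with planted motifs and an independent
    brute-force placement oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
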