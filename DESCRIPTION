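Package: epimapr
Title: Integrated CD4+ T-Cell Epitope Mapping from Peptide Pools and
    MHC-II Immunopeptidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies protein-derived CD4+ T-cell epitopes by integrating
    overlapping-peptide-pool T-cell activation assays with MHC class II
    immunopeptidomics (MAPPs) identifications. Provides the overlapping
    15-mer library and pool design, simulated-annealing selection of an
    HLA-representative donor cohort, one-sided Fisher exact responder
    calling with Holm step-down adjustment, DRB1 allele-association and
    frequency-weighted promiscuity scoring, Expect-Value filtering and
    residue-level merging of immunopeptidomics identifications, the
    donor-matched residue-level integration that yields the final epitope
    list with its cumulative population allele frequency, and a seeded
    synthetic-data generator emulating every input table so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
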