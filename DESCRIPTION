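Package: hogmapper
Title: Alignment-Free Assignment of Proteins to Hierarchical Orthologous
    Group Subfamilies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns protein sequences to gene families (root-HOGs) and
    subfamilies (sub-HOGs) without alignment, using a precomputed table of
    evolutionarily informed k-mers: each k-mer is attributed, within every
    family, to the last common ancestor of the subfamilies that contain it,
    so that shared ancestral sequence does not drag queries into
    over-specific subfamilies. Includes a Smith-Waterman closest-sequence
    baseline, a two-level (family and subfamily) precision/recall
    validation framework with closest-sequence configuration analysis, and
    a synthetic gene-family generator with duplication nesting and
    post-duplication rate acceleration, so the whole system is testable at
    desk scale with known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    data.table,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
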