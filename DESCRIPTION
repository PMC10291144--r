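Package: xreact
Title: Off-Target Cross-Reactivity Risk Screening for T-Cell Epitopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free screening of HLA class I immunopeptidomes for
    self-peptides that resemble a therapeutic T-cell target. Peptides are
    encoded in a PCA-reduced amino-acid biochemical descriptor space built
    from the AAIndex property collection, candidate self-peptides are ranked
    by a length-normalized (optionally TCR-contact-weighted) relatedness
    score against the query, p-values are assigned from a Monte-Carlo
    Gaussian null, and hits are annotated with tissue expression, predicted
    HLA binding, and immunogenicity evidence for off-target risk
    prioritization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
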