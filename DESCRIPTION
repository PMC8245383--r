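Package: glycosequon
Title: N-Glycosylation Sequon Scanning and Splice-Isoform Glycosite Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting and comparing N-glycosylation sequons
    (N-x-S/T, x != P, with optional non-canonical NxC/NxV classes) in
    protein sequences. Maps sequon positions between canonical proteins
    and alternatively spliced isoforms by global pairwise alignment and
    classifies every site as retained, shifted, lost or gained; annotates
    genes with surface prediction consensus (SPC) scores; tests sequon
    motif enrichment against a composition-preserving permutation null;
    and integrates RNA-seq transcript abundance with glycopeptide
    spectral-count evidence across differentiation timepoints, including
    volcano-style differential tables and max-normalized evidence
    profiles. A synthetic-data generator produces all pipeline inputs
    with coordinate-derived ground truth so every stage can be validated
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
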