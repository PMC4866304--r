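Package: dmsplice
Title: Deep Mutational Scanning Analysis of Exon Splicing Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for deep mutational scanning of alternative
    splicing with doped oligonucleotide libraries, built around human FAS/CD95
    exon 6. Converts amplicon reads from input and spliced-output channels into
    variant counts, computes wild-type-normalised median-based enrichment
    scores, classifies single-mutation effects with Welch tests under
    Benjamini-Hochberg FDR control, calibrates enrichment scores to percent
    spliced in (PSI) with an exponential fit, compares mutational robustness
    across near-neutral genetic backgrounds with coverage-matched read
    resampling, and maps pairwise epistasis as residuals from a per-replicate
    linear no-interaction expectation. Includes a doped-library simulator that
    generates ground-truth splicing landscapes and sequencing counts so every
    stage can be validated against known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    seqinr,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
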