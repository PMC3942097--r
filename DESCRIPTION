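Package: hATpipe
Title: Discovery and Horizontal-Transfer Analysis of hAT Transposons and
    Their MITE Derivatives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Annotation and molecular-evolution toolkit for class II (hAT
    superfamily) transposable elements. Implements in-silico PCR with
    degenerate IUPAC primers, detection of terminal inverted repeats (TIRs)
    and target site duplications (TSDs), classification of element copies
    into complete elements, MITEs and fragments, exon-model splicing and
    translation, pairwise evolutionary distances (p-distance and Tamura
    3-parameter) with neighbor-joining tree construction, and a chi-squared
    classifier that contrasts transposon divergence with nuclear-gene
    divergence to distinguish horizontal transfer from vertical
    transmission. A transposition-realistic simulator (TSD-duplicating
    insertions, internal-deletion MITE derivation, substitution-model
    sequence evolution) generates fully ground-truthed test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    ape,
    stats
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    jsonlite
Config/testthat/edition: 3
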