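Package: gtctopo
Title: Membrane Topology and Luminal Motif Models for GT-C Glycosyltransferases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers membrane topology models and luminal catalytic-motif
    annotations for multi-spanning glycosyltransferase (GT-C) families from
    multiple sequence alignments. Provides diverse-homolog selection,
    reference-numbered consensus hydropathy profiling and transmembrane
    segmentation (including splitting of over-long hydrophobic runs),
    positive-inside/dilysine orientation, sequence-logo information content,
    a degenerate protein motif grammar scanned within predicted loops,
    topology-organization classification, a luminal-versus-cytoplasmic
    conservation permutation test, a synthetic family generator with known
    ground truth, and monoisotopic m/z calculation for C-mannosylated
    tryptic glycopeptides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
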