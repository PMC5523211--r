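Package: barcodegap
Title: DNA Barcode Species Delimitation from COI Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Distance- and character-based species delimitation from aligned
    DNA barcode (COI) sequences. Computes pairwise p-distances under pairwise
    deletion, per-species intra- and interspecific distance summaries,
    neighbor-joining trees with column-bootstrap supports and per-species
    monophyly tests, alignment site statistics (variable and
    parsimony-informative sites), and "pure" diagnostic nucleotide sites fixed
    within one species and absent from all others. Includes a seeded synthetic
    barcode-data generator with planted diagnostics and known distance
    structure, so the whole pipeline is testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
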