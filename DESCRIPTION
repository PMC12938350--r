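Package: mitoarch
Title: Mitogenome Architecture, tRNA Rearrangement and Comparative Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the comparative analysis of annotated circular
    mitochondrial genomes, built around the tRNA gene-order rearrangements of
    snailfishes (Liparidae). Parses annotation feature tables and GenBank
    flat files with circular coordinate arithmetic; computes base composition,
    AT/GC strand skews, codon usage and relative synonymous codon usage (RSCU)
    under the vertebrate mitochondrial code; extracts and classifies the
    WANCY tRNA cluster between ND2 and COI; searches exhaustively for minimal
    tandem-duplication-random-loss (TDRL) scenarios explaining rearranged
    orders; classifies tRNA stem base pairs (Watson-Crick, G-U wobble, A-C);
    maps discrete characters onto phylogenies with generalized Fitch
    parsimony and a tip-permutation clustering test; and generates synthetic
    annotated mitogenomes with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    seqinr,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    phangorn,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
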