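Package: barcodeEval
Title: Evaluation of DNA Barcode Marker Performance from Aligned Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to assess how well a short DNA barcode marker (such as
    the nuclear ribosomal ITS2 spacer) discriminates taxa within a family.
    Provides Kimura two-parameter pairwise distances under pairwise
    deletion with full per-pair bookkeeping, alignment variability
    statistics (conserved, variable, parsimony-informative and singleton
    sites, overall mean distance), intra- and interspecific divergence
    indices (all/minimum interspecific distance, all intraspecific
    distance, theta, coalescent depth), barcode-gap distance-frequency
    distributions, and leave-one-out species identification scoring by
    Best Match, Best Close Match and a best-hit (BLAST1-style) criterion,
    all computable at nested taxonomic levels (species complex, genus,
    subfamily, family). A seeded simulator generates species/genus
    structured alignments under a K2P substitution process so every stage
    of the analysis is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
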