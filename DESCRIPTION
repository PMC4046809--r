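Package: HGTscan
Title: Screening and Curation of Horizontal Gene Transfer in Phagotrophic Protist Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and curation of horizontally acquired genes in a focal
    eukaryotic genome from precomputed homology searches and gene trees, after
    the phylogenomic surveys of phagotrophic protists such as the
    choanoflagellate Monosiga brevicollis. Implements taxonomic grouping of
    BLAST-style tabular hits, alien-index (bit-score ratio) candidate
    screening, bootstrap-supported monophyly tests on unrooted gene trees,
    consensus curation across detectors with phyletic-distribution and
    direction rules, collapsing of acquired paralogs into transfer events,
    homolog sharing with a second proteome, and summary reporting. A seeded
    simulator plants transfers into synthetic gene families so every stage is
    testable end to end without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Phylogenetics, ComparativeGenomics, Software
RoxygenNote: 7.3.3
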