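Package: poregraph
Title: Hydrogen-Bond Network Graphs and Pore Analysis for Channelrhodopsin Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative structural analysis of homologous microbial rhodopsin
    channels: parsing and entity classification of atomic models, residue
    correspondence by pairwise global sequence alignment, Kabsch superposition
    with residue-level displacement, distance-criterion hydrogen-bond network
    graphs with conserved/difference graph comparison and membrane-plane
    projection, and grid-based cavity and bottleneck-tunnel detection along the
    putative ion-conduction pathway. Includes a deterministic synthetic-fixture
    generator (alpha-helical bundles with planted hydrogen bonds, cavities and
    decoy entities) so that every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
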