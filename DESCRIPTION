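Package: cgpdChord
Title: CGPD-Tetramer Construction and Chord-Diagram Visualization for
    Curated Toxicogenomic Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds chemical-gene-phenotype-disease (CGPD) tetramers from
    locally supplied curated-interaction tables by requiring all five
    pairwise supporting relations (chemical-gene, chemical-phenotype,
    chemical-disease, gene-phenotype, gene-disease), with optional
    ontology-descendant expansion of query terms.  Decomposes tetramer
    sets into directed dimer edges with tetramer-support frequencies,
    computes a frequency-proportional circular chord-diagram layout
    (sectors, gaps, ribbons, gradient class palettes, label anchors)
    with its own geometry engine, and renders the layout to SVG or PNG.
    Includes seeded synthetic-fixture generators with brute-force
    oracle closures, CSV readers and writers for the CTD download
    dialect, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, grDevices, graphics, data.table, jsonlite
Suggests: testthat (>= 3.0.0), xml2, igraph, yaml, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
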