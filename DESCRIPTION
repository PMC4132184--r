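Package: cohesionScreen
Title: Interactome Cohesiveness Testing and RNAi Phenotype Screen Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for the downstream analysis of tandem affinity
    purification mass spectrometry (TAP-MS) interactor screens in model
    organisms. Filters raw hit tables to high-confidence candidate
    interactors (replicate reproducibility, negative-control subtraction,
    contaminant blocklists), assembles the candidate interaction network
    from a reference interactome with a two-or-more-links parsimony
    expansion to first-order neighbours, quantifies network cohesiveness
    with a physical interaction enrichment (PIE) score against a
    degree-matched permutation null, and scores categorical RNAi phenotype
    screens with Fisher's exact tests. A synthetic-data generator
    (configuration-model and uniform random reference graphs, planted
    cohesive modules via degree-preserving edge swaps, simulated TAP-MS
    runs and multinomial phenotype screens) supports testing and power
    analysis without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'io.R'
    'filter.R'
    'network.R'
    'pie.R'
    'rnai.R'
    'synth.R'
    'pipeline.R'
    'cohesionScreen-package.R'
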