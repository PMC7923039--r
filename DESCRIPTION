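Package: fluxnode
Title: Metabolite-Centric Constraint-Based Analysis of Genome-Scale Metabolic Models
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolbox for constraint-based analysis of genome-scale metabolic
    networks with a metabolite-centric focus. Implements flux balance analysis
    (FBA), flux variability analysis (FVA) with warm-started linear programs,
    minimization of metabolic adjustment (MOMA), reaction knockout scans and
    batch FBA, together with metabolite flux minimization (MFM), metabolite
    essentiality ranking, split-ratio analysis of producer/consumer fluxes at
    each metabolite node, and bipartite network export with split-ratio edge
    labels. Iterative dead-end reduction is available as preprocessing for
    every optimization. Models are read and written as human-readable reaction
    lists with detached scenario files, SBML (Level 2, and Level 3 with the
    fbc extension), and COBRA-style JSON. Curation utilities cover synonym
    based metabolite-name normalization, automated plausibility checks, and
    reaction directionality assignment from Gibbs free energies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    BiocGenerics,
    xml2,
    jsonlite,
    igraph,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    quadprog
Config/testthat/edition: 3
biocViews: SystemsBiology, Metabolomics, Network, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'model-core.R'
    'reduction.R'
    'simplex.R'
    'solver.R'
    'flux-analysis.R'
    'metabolite-centric.R'
    'graph-export.R'
    'curation.R'
    'io-json.R'
    'io-sbml.R'
    'io-rxn.R'
    'fixtures.R'
    'cli.R'
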