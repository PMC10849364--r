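Package: melanet
Title: Seeded Protein-Protein Interaction Network Modeling of Melanoma Risk Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An in-silico pipeline for building and interrogating a disease
    risk-gene network model of cutaneous melanoma. Provides GWAS locus-to-gene
    prioritization (physical-distance and linkage-disequilibrium loci, skin
    eQTL joins, biotype keyword filtering), merging of GWAS, familial and
    somatic risk-gene lists with provenance, construction of level-zero
    (seed-seed) and level-one (seed-plus-bridge) protein-protein interaction
    networks from literature interaction tables with quality control, greedy
    modularity community detection with deterministic tie-breaking and cluster
    quality control, Monte-Carlo gene-set overlap enrichment against the
    network model, two-group expression re-analysis (Welch t, Bonferroni,
    nested fold-change classes), differential-expression overlays, keyword
    based semantic grouping of enrichment terms, and a synthetic-data module
    that generates every pipeline input with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'clustering.R'
    'enrichment-stats.R'
    'gwas-prioritization.R'
    'interactome.R'
    'pipeline.R'
    'seed-table.R'
    'semantic-grouping.R'
    'synthetic-data.R'
    'utils.R'
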