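Package: orthonet
Title: Multilevel Bidirectional-Best-Hit Orthology and Ortholog/Paralog
    Gene Networks
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects orthologs between two plant species as Bidirectional
    Best Hits (BBH) confirmed independently at the gene, transcript and
    protein sequence levels, attaches within-species paralogs at stringent
    (1e-50) and loose (1e-3) e-value thresholds, organises the resulting
    relationships into connected-component gene networks, classifies
    species-specific genes, reconciles functional annotations (description
    transfer under a 90/90 identity/coverage filter, character-level
    description similarity, InterPro domain agreement), and clusters
    ortholog expression profiles with Figure-of-Merit-guided K-means under
    Pearson correlation distance, hierarchical sub-clustering and
    hypergeometric GO enrichment with Hochberg adjustment. A synthetic
    two-species fixture generator with planted ground truth makes every
    stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
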