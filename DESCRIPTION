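Package: mvmarker
Title: Multi-View Multi-Objective Gene Marker Selection by Archived
    Simulated Annealing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Unsupervised selection of relevant, non-redundant gene markers
    from two-class expression data by multi-view multi-objective clustering.
    Genes are clustered simultaneously under two dissimilarity views -- an
    expression correlation-distance view and an integrated functional view
    combining Gene Ontology semantic similarity, weighted protein-protein
    interaction neighbourhood similarity and BLAST bit-score sequence
    similarity -- with an archived multi-objective simulated annealing
    (AMOSA) optimizer over three objectives: average signal-to-noise ratio
    of consensus centers, average pairwise correlation distance among
    centers, and the agreement index between the two view partitions.
    Pareto-front solutions are ensembled by majority voting, cluster
    centers are extracted as candidate genes, and genes recurring across
    independent runs are reported as markers with regulation modes.
    Includes readers for the standard input formats (expression TSV/CSV,
    OBO 1.2, GAF/TSV annotations, weighted PPI edge lists, BLAST tabular
    output), internal and external cluster validity indices, sample
    classification on original and reduced gene spaces, and a synthetic
    data generator that plants cluster, class and functional structure in
    all inputs for end-to-end offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    pheatmap,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
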