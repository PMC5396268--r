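Package: clusterrank
Title: Ranking Clusters of Docked Protein-Protein Complexes by Pairwise
    Cluster Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A machine-learning protocol for ranking clusters of docked
    protein-protein complexes. Docked poses are clustered by ligand
    root-mean-square deviation (LRMSD) with the GROMOS neighbour-count
    algorithm, each cluster is characterised by five-point summaries
    (minimum, quartiles, median, maximum) of molecular descriptor
    distributions plus cluster size, and an extremely randomized trees
    classifier is trained on pairwise cluster comparisons to predict which
    of two clusters holds the lower-LRMSD pose. Clusters are ranked by
    predicted win counts over all pairwise comparisons. Includes CAPRI-style
    quality measures (LRMSD, IRMSD, FNAT), steric-clash filtering,
    enrichment sub-clustering, descriptor screening (Mann-Whitney U,
    Pearson correlation), recursive feature elimination, dimensionality
    reduction sweeps (PCA, factor analysis, kernel PCA), and a synthetic
    benchmark generator with planted near-native clusters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    ranger,
    kernlab,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
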