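Package: gvclust
Title: Structure-Informed Orthogroup Clustering and Interactome Analysis for
    Giant Viruses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A toolkit for classifying orphan-rich giant-virus proteomes and
    analysing their protein-protein interaction networks. Implements two-stage
    sequence-then-structure orthogroup clustering on precomputed pairwise
    similarity tables, a connectivity-based cluster-merge step, last-common-
    ancestor taxonomic annotation of clusters, paralog and virion-shape
    classification, IP-MS differential-enrichment statistics (replicate
    filtering, normalisation, missing-value imputation, empirical-Bayes
    moderated t-tests), bait summary networks with Louvain community
    detection, Fisher-exact enrichment machinery, homologous PDB-complex
    ranking with interface-contact networks, and seeded synthetic-data
    generators with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
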