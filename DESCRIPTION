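Package: lpianet
Title: Latent Pathway Identification Analysis from Differential
    Expression and Gene-Set Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies latent biological pathways from a differential
    expression table and two gene-set collections (KEGG pathways and GO
    biological-process terms). Builds a DE-weighted pathway-GO bipartite
    graph (Jaccard overlap times the median DE magnitude of shared
    genes), projects it to a weighted pathway-pathway network, ranks
    pathways by eigenvector centrality via power iteration, and attaches
    bootstrap p-values with step-down max-statistic multiplicity
    adjustment. Includes native overrepresentation statistics
    (hypergeometric test, Benjamini-Hochberg correction, rich ratio),
    Cytoscape-ready network export (edge/node TSV, SIF, GraphML), a
    synthetic-data generator with a planted latent pathway for
    end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    optparse,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
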