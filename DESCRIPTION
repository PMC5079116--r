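Package: phenonet
Title: Neuronal Phenotype Discovery and Paracrine Interaction Networks from Single-Cell qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering transcriptional phenotypes in single-cell
    qPCR data and inferring directed paracrine/autocrine interaction networks
    between them. Implements two-step -ddCt normalization with
    housekeeping-gene stability ranking, permutation-calibrated Pearson
    correlation networks over genes and cells, leading-eigenvector modularity
    community detection with residual-group pooling, cluster validation
    (silhouette scores, PCA, classical MDS, gene-module clustering, rank-sum
    spatial tests), per-cell ligand-receptor signaling-regime classification
    with one-sided enrichment testing, and construction of the resulting
    directed group-interaction network. Includes a synthetic-data generator
    with planted phenotype groups, dropout, spatial bias and
    ligand-receptor structure so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    cluster,
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
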