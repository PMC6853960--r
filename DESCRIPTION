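Package: comorbnet
Title: Disease Comorbidity Inference from Heterogeneous miRNA-Gene-Disease Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers disease-disease (comorbidity) relationships from a
    heterogeneous network built from four layers: disease-miRNA, miRNA-gene,
    disease-gene and protein-protein (gene-gene) interactions. Meta-path
    constrained random walks generate typed node sequences, a heterogeneous
    skip-gram model with type-aware negative sampling learns node embeddings
    by stochastic gradient descent, and cosine similarity between
    (optionally concatenated) disease vectors ranks candidate comorbid
    pairs. Includes the miRNA-overlap Jaccard baseline, ROC/PR evaluation
    against labeled disease pairs, meta-path instance enumeration for
    mechanistic interpretation, a planted-partition synthetic network
    generator, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    xml2,
    digest,
    Rtsne,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
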