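Package: dgembed
Title: Disease and Gene Embeddings from Inpatient Discharge Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Learns low-dimensional vector representations of diseases from
    the co-occurrence structure of inpatient discharge records, treating each
    record's ordered diagnosis list as a sentence and training a skip-gram
    model with negative sampling. A joint variant additionally embeds genes,
    using curated disease-gene association tables so that each gene attached
    to a central disease also predicts that disease's record context, placing
    diseases and genes in a single vector space. Cosine nearest-neighbour
    retrieval over the learned space supports disease phenotyping and
    disease-gene discovery, evaluated with precision-at-K and gene-overlap
    metrics against shared-gene and held-out-gene ground truth. Comorbidity
    network, spectral and modularity-matrix baselines, trivial gene
    predictors, and a synthetic discharge-record generator with planted
    phenotype clusters are included so the full pipeline can be exercised
    without access to licensed EHR data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
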