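Package: molclust
Title: Benchmarking Clusterings of Small-Molecule Fingerprint Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for clustering chemical libraries represented as binary
    Morgan fingerprints and for judging how good the resulting clusters are.
    Implements pairwise Tanimoto similarity with block-wise memory use, a
    nearest-neighbour outlier filter, three clustering routes (Ward
    agglomeration on Tanimoto distances, Taylor-Butina exclusion-sphere
    clustering, and agglomerative clustering of a low-dimensional UMAP
    embedding), the silhouette, Calinski-Harabasz and Davies-Bouldin validity
    indices, average inter/intra-cluster similarity matrices, elbow-method
    selection of the cluster number, and a synthetic fingerprint generator
    with planted clusters and injected outliers for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
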