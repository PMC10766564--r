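Package: cartonet
Title: Interpretable Network Cartographs from Node Similarity Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds interpretable 2D and 3D network layouts ("cartographs") by
    encoding chosen structural or functional node characteristics into an
    N x N cosine-similarity matrix and embedding it with t-SNE or UMAP.
    Provides five layout families (global via random walk with restart,
    local via shared neighborhoods, importance via centrality profiles,
    functional via binary annotations, and combined), four map types
    (2D/3D portraits, topographic maps, geodesic maps), deterministic
    generators for benchmark model networks (Cayley tree, cubic grid,
    torus lattice), synthetic annotation fixtures, and a layout-quality
    benchmark comparing shortest-path and layout Euclidean distances via
    Pearson correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    Rtsne,
    uwot,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
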