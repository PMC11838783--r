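Package: mcpathway
Title: Mixed-Curvature Product-Manifold Embeddings for Biological Pathway Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns distortion-minimizing node embeddings of biological
    pathway graphs on Cartesian products of spherical, hyperbolic
    (hyperboloid model) and Euclidean spaces via Riemannian stochastic
    gradient descent, sweeps product-space signatures under a fixed total
    dimension budget to select the lowest-distortion geometry per graph,
    and trains a mixed-curvature product graph convolutional network
    (tangent-space message passing with a Fermi-Dirac distance decoder,
    optimized with Riemannian Adam) to predict missing protein-protein
    interaction edges. Includes Euclidean baselines (node2vec,
    graph-Laplacian eigenvectors, distortion-trained Euclidean
    embeddings), a post-hoc scaling optimization for fair distortion
    comparison, edge-split/negative-sampling/AUROC/AP evaluation
    utilities, and synthetic pathway-scale graph generators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
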