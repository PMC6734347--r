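Package: heatlink
Title: Heat-Diffusion Link Prediction on Two-Layer Tumor-Gene Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts missing tumor-sample to gene associations by seeding heat
    at a tumor's known genes and diffusing it over a gene-gene interaction
    network (two-layer graph). Implements unweighted and degree-normalized heat
    matrices, a PageRank-style teleport term, exact (matrix-exponential) and
    linear-cost discrete diffusion, classical link-prediction baselines
    (common neighbors, Jaccard, Adamic/Adar, preferential attachment, resource
    allocation, truncated Katz, personalized PageRank, random), edge-holdout
    cross-validation with rank-based AUC-ROC and AUC-PR, degree-preserving
    graph randomization with permutation p-values and Bonferroni correction,
    and a synthetic two-layer graph generator with a plantable diffusion
    signal. Reads STRING-style weighted and BioGRID-style unweighted edge
    lists, including protein-to-gene network collapse.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
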