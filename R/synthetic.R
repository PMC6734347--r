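#' The four-gene toy two-layer network
#'
#' A single tumor (`TUMORX`) linked to genes A, B and C (but not D), over an
#' interaction layer with edges A-B and C-D. Gene D is the diffusion
#' target: it receives heat only through its interaction with C.
#'
#' @return a [two_layer_graph].
#' @export
toy_fixture <- function() {
  l1 <- bipartite_layer(
    data.frame(tumor = "TumorX", gene = c("A", "B", "C")),
    genes = c("A", "B", "C", "D")
  )
  l2 <- interaction_layer(
    data.frame(gene1 = c("A", "C"), gene2 = c("B", "D")),
    genes = c("A", "B", "C", "D")
  )
  two_layer_graph(l1, l2)
}

#' The literal 4x4 toy heat matrix
#'
#' The toy example's heat matrix as printed in its source write-up, kept
#' verbatim as a fixture constant. Note its A-B block is asymmetric even
#' though the toy graph is undirected -- [build_heat_matrix_unweighted()]
#' on [toy_fixture()] gives the symmetric operator instead; only the Gene-D
#' behavior of the printed matrix is internally consistent.
#'
#' @return a dense 4x4 matrix with genes A-D as dimnames.
#' @export
toy_printed_heat_matrix <- function() {
  matrix(
    c(-1, 1, 0, 0,
      0, -1, 0, 0,
      0, 0, -1, 1,
      0, 0, 1, -1),
    nrow = 4, byrow = TRUE,
    dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D"))
  )
}

#' Generate a synthetic two-layer graph with a plantable diffusion signal
#'
#' Builds an interaction layer with a skewed (preferential-attachment) or
#' Erdos-Renyi degree distribution, then samples sparse tumor-gene edges:
#' each tumor's first gene is uniform and each later gene is, with
#' probability `planted_fraction`, drawn from the layer-2 neighbors of the
#' tumor's already-chosen genes (a diffusion-recoverable signal) and
#' otherwise uniform (noise). A held-out subset of edges (at least one
#' retained edge per tumor) is designated for link-recovery experiments.
#' When planting finds no unused neighbor it falls back to a uniform draw
#' and reports the count.
#'
#' @param n_tumors,n_genes numbers of tumor samples and genes.
#' @param bipartite_density expected fraction of realized tumor-gene links
#'   (default 0.0133, a realistic link prevalence for this task).
#' @param gene_graph layer-2 model: `"preferential_attachment"` (default;
#'   high sparsity, right-skewed degrees) or `"erdos_renyi"`.
#' @param pa_m edges attached per new gene under preferential attachment.
#' @param er_p edge probability under Erdos-Renyi.
#' @param weighted draw edge weights ~ uniform(0.1, 1)?
#' @param planted_fraction probability that a tumor's non-first edges point
#'   at layer-2 neighbors of its other genes, in \[0, 1\].
#' @param holdout_fraction fraction of each tumor's edges designated as
#'   held out (default 0.2).
#' @param seed integer seed; the same seed gives byte-identical edge lists.
#' @return a list with `graph` (a [two_layer_graph]) and `held_out` (data
#'   frame of held-out `tumor`, `gene` label pairs, disjoint from the
#'   retained edges).
#' @export
generate_two_layer <- function(n_tumors = 200L, n_genes = 150L,
                               bipartite_density = 0.0133,
                               gene_graph = c("preferential_attachment",
                                              "erdos_renyi"),
                               pa_m = 2L, er_p = 0.05, weighted = FALSE,
                               planted_fraction = 1,
                               holdout_fraction = 0.2, seed = 1L) {
  gene_graph <- match.arg(gene_graph)
  .assert(n_tumors >= 1 && n_genes >= 2, "need >= 1 tumor and >= 2 genes")
  .assert(bipartite_density > 0 && bipartite_density <= 1,
          "bipartite_density must lie in (0, 1]")
  .assert(bipartite_density * n_tumors * n_genes >= 1,
          "expected edge count below 1; raise the density")
  .assert(planted_fraction >= 0 && planted_fraction <= 1,
          "planted_fraction must lie in [0, 1]")
  set.seed(as.integer(seed))
  genes <- sprintf("G%04d", seq_len(n_genes))
  tumors <- sprintf("T%04d", seq_len(n_tumors))

  ig <- if (gene_graph == "preferential_attachment") {
    igraph::sample_pa(n_genes, m = pa_m, directed = FALSE)
  } else {
    igraph::sample_gnp(n_genes, er_p)
  }
  el <- igraph::as_edgelist(ig, names = FALSE)
  w <- if (weighted) stats::runif(nrow(el), 0.1, 1.0) else NULL
  l2 <- interaction_layer(
    data.frame(gene1 = genes[el[, 1]], gene2 = genes[el[, 2]]),
    weights = w, genes = genes
  )
  nbr <- lapply(igraph::as_adj_list(ig), as.integer)

  fallbacks <- 0L
  edge_t <- integer(0)
  edge_g <- integer(0)
  held_t <- integer(0)
  held_g <- integer(0)
  for (t in seq_len(n_tumors)) {
    k <- stats::rbinom(1, n_genes, bipartite_density)
    if (k == 0) next  # tumor stays isolated; keeps realized density unbiased
    chosen <- sample.int(n_genes, 1)
    while (length(chosen) < k) {
      pool <- setdiff(unique(unlist(nbr[chosen])), chosen)
      plant <- stats::runif(1) < planted_fraction
      if (plant && length(pool) > 0) {
        g <- .sample1(pool)
      } else {
        if (plant) fallbacks <- fallbacks + 1L
        g <- .sample1(setdiff(seq_len(n_genes), chosen))
      }
      chosen <- c(chosen, g)
    }
    edge_t <- c(edge_t, rep.int(t, k))
    edge_g <- c(edge_g, chosen)
    if (k >= 2) {
      n_h <- min(floor(holdout_fraction * k), k - 1L)
      if (n_h >= 1) {
        idx <- (2:k)[sample.int(k - 1L, n_h)]  # never hold out the first gene
        held_t <- c(held_t, rep.int(t, n_h))
        held_g <- c(held_g, chosen[idx])
      }
    }
  }
  if (fallbacks > 0) {
    message(fallbacks, " planted edge(s) fell back to uniform draws")
  }
  l1 <- bipartite_layer(
    data.frame(tumor = tumors[edge_t], gene = genes[edge_g]),
    tumors = tumors, genes = genes
  )
  list(
    graph = two_layer_graph(l1, l2),
    held_out = data.frame(tumor = tumors[held_t], gene = genes[held_g])
  )
}
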