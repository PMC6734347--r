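#' Bipartite tumor-to-gene layer
#'
#' Layer 1 of the two-layer graph: a directed bipartite "hasGene" relation
#' from tumor samples to genes. Gene symbols are uppercased before indexing;
#' tumor identifiers are kept verbatim. Duplicate edges are collapsed.
#'
#' @param pairs two-column data frame or matrix of (tumor label, gene label)
#'   edges.
#' @param tumors,genes optional label universes; defaults to the labels seen
#'   in `pairs` (order of first appearance). Extra labels give isolated nodes.
#' @return an object of class `bipartite_layer`: a list with character vectors
#'   `tumors` and `genes` and an integer edge matrix `edges` (columns
#'   `tumor`, `gene`, 1-based positions).
#' @export
bipartite_layer <- function(pairs, tumors = NULL, genes = NULL) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  .assert(ncol(pairs) >= 2, "bipartite edges need two columns (tumor, gene)")
  t_lab <- as.character(pairs[[1]])
  g_lab <- toupper(as.character(pairs[[2]]))
  tumors <- as.character(tumors %||% unique(t_lab))
  genes <- toupper(as.character(genes %||% unique(g_lab)))
  .assert(!anyDuplicated(tumors), "duplicate tumor labels in index")
  .assert(!anyDuplicated(genes), "duplicate gene labels in index")
  ti <- match(t_lab, tumors)
  gi <- match(g_lab, genes)
  .assert(!anyNA(ti), "edge references a tumor absent from the tumor index")
  .assert(!anyNA(gi), "edge references a gene absent from the gene index")
  edges <- cbind(tumor = ti, gene = gi)
  edges <- edges[!duplicated(.edge_keys(edges, length(genes))), , drop = FALSE]
  structure(
    list(tumors = tumors, genes = genes, edges = edges),
    class = "bipartite_layer"
  )
}

#' Gene-gene interaction layer
#'
#' Layer 2 of the two-layer graph: an undirected, optionally weighted gene
#' interaction network. Self-loops are dropped (with a message), duplicate
#' pairs are collapsed keeping the maximum weight, and weights must lie in
#' (0, 1].
#'
#' @param pairs two-column data frame or matrix of (gene, gene) label pairs.
#' @param weights optional numeric vector of edge weights in (0, 1]; `NULL`
#'   means an unweighted layer (implicit weight 1).
#' @param genes optional gene label universe (uppercased); defaults to the
#'   labels seen in `pairs`.
#' @return an object of class `interaction_layer`: a list with `genes`
#'   (character), `edges` (integer matrix, columns `i`, `j`, canonicalized
#'   so `i < j`) and `weights` (numeric or `NULL`).
#' @export
interaction_layer <- function(pairs, weights = NULL, genes = NULL) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  .assert(ncol(pairs) >= 2, "interaction edges need two columns (gene1, gene2)")
  a_lab <- toupper(as.character(pairs[[1]]))
  b_lab <- toupper(as.character(pairs[[2]]))
  genes <- toupper(as.character(genes %||% unique(c(a_lab, b_lab))))
  .assert(!anyDuplicated(genes), "duplicate gene labels in index")
  ai <- match(a_lab, genes)
  bi <- match(b_lab, genes)
  .assert(!anyNA(ai) && !anyNA(bi), "edge references a gene absent from the index")
  if (!is.null(weights)) {
    weights <- as.numeric(weights)
    .assert(length(weights) == length(ai), "one weight per edge required")
    .assert(all(is.finite(weights)) && all(weights > 0) && all(weights <= 1),
            "interaction weights must lie in (0, 1]")
  }
  loop <- ai == bi
  if (any(loop)) {
    message(sum(loop), " self-loop(s) dropped from interaction layer")
    ai <- ai[!loop]; bi <- bi[!loop]
    if (!is.null(weights)) weights <- weights[!loop]
  }
  i <- pmin(ai, bi)
  j <- pmax(ai, bi)
  if (length(i)) {
    key <- .edge_keys(cbind(i, j), length(genes))
    if (anyDuplicated(key)) {
      ## duplicates collapse to the maximum weight
      ord <- order(key, if (is.null(weights)) rep(1, length(key)) else -weights)
      keep <- !duplicated(key[ord])
      sel <- ord[keep]
      i <- i[sel]; j <- j[sel]
      if (!is.null(weights)) weights <- weights[sel]
    }
  }
  structure(
    list(genes = genes, edges = cbind(i = i, j = j), weights = weights),
    class = "interaction_layer"
  )
}

#' Assemble a two-layer tumor-gene graph
#'
#' Unifies the gene universes of the bipartite layer and the interaction
#' layer (union, in order of first appearance: layer-1 genes first). Genes
#' seen in only one layer are kept as isolated nodes in the other, so every
#' gene shares one index across layers.
#'
#' @param layer1 a [bipartite_layer].
#' @param layer2 an [interaction_layer].
#' @return an object of class `two_layer_graph`: list with elements `layer1`
#'   and `layer2` over the shared gene index.
#' @export
two_layer_graph <- function(layer1, layer2) {
  .assert(inherits(layer1, "bipartite_layer"), "layer1 must be a bipartite_layer")
  .assert(inherits(layer2, "interaction_layer"), "layer2 must be an interaction_layer")
  genes <- union(layer1$genes, layer2$genes)
  l1 <- layer1
  l1$edges <- cbind(
    tumor = layer1$edges[, 1],
    gene = match(layer1$genes, genes)[layer1$edges[, 2]]
  )
  l1$genes <- genes
  l2 <- layer2
  map2 <- match(layer2$genes, genes)
  if (nrow(layer2$edges)) {
    i <- map2[layer2$edges[, 1]]
    j <- map2[layer2$edges[, 2]]
    l2$edges <- cbind(i = pmin(i, j), j = pmax(i, j))
  } else {
    l2$edges <- cbind(i = integer(0), j = integer(0))
  }
  l2$genes <- genes
  structure(list(layer1 = l1, layer2 = l2), class = "two_layer_graph")
}

#' Graph summary counts
#'
#' Node and edge counts for a two-layer graph, in the style of a network
#' summary table: tumor samples, genes, hasGene relations, interaction edges.
#'
#' @param graph a [two_layer_graph].
#' @return a list of counts (`n_tumors`, `n_genes`, `n_has_gene`,
#'   `n_interactions`, `bipartite_density`).
#' @export
graph_summary <- function(graph) {
  .assert(inherits(graph, "two_layer_graph"), "need a two_layer_graph")
  list(
    n_tumors = length(graph$layer1$tumors),
    n_genes = length(graph$layer1$genes),
    n_has_gene = nrow(graph$layer1$edges),
    n_interactions = nrow(graph$layer2$edges),
    bipartite_density = bipartite_density(graph$layer1)
  )
}

#' Bipartite edge density
#'
#' The proportion of realized tumor-gene links among all possible pairs --
#' the prevalence of positives in the link-prediction task.
#'
#' @param layer1 a [bipartite_layer].
#' @return a number in \[0, 1\].
#' @export
bipartite_density <- function(layer1) {
  .assert(inherits(layer1, "bipartite_layer"), "need a bipartite_layer")
  nrow(layer1$edges) / (length(layer1$tumors) * length(layer1$genes))
}

#' Sparse adjacency of the interaction layer
#'
#' @param layer2 an [interaction_layer].
#' @param weighted use stored weights if present (`TRUE`, default) or the
#'   0/1 pattern (`FALSE`).
#' @return a symmetric sparse `Matrix` with zero diagonal.
#' @export
interaction_adjacency <- function(layer2, weighted = TRUE) {
  n <- length(layer2$genes)
  e <- layer2$edges
  w <- if (weighted && !is.null(layer2$weights)) layer2$weights
       else rep(1, nrow(e))
  Matrix::sparseMatrix(
    i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]), x = c(w, w),
    dims = c(n, n), dimnames = list(layer2$genes, layer2$genes)
  )
}

#' Sparse adjacency of the bipartite layer
#'
#' @param layer1 a [bipartite_layer].
#' @param edges optional integer edge matrix (e.g. a training subset);
#'   defaults to all edges.
#' @return a sparse tumors-by-genes 0/1 `Matrix`.
#' @export
bipartite_adjacency <- function(layer1, edges = layer1$edges) {
  Matrix::sparseMatrix(
    i = edges[, 1], j = edges[, 2], x = rep(1, nrow(edges)),
    dims = c(length(layer1$tumors), length(layer1$genes)),
    dimnames = list(layer1$tumors, layer1$genes)
  )
}

#' @exportS3Method base::print
print.bipartite_layer <- function(x, ...) {
  cat("<bipartite_layer> ", length(x$tumors), " tumors, ", length(x$genes),
      " genes, ", nrow(x$edges), " hasGene edges\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::print
print.interaction_layer <- function(x, ...) {
  cat("<interaction_layer> ", length(x$genes), " genes, ", nrow(x$edges),
      if (is.null(x$weights)) " unweighted" else " weighted",
      " interaction edges\n", sep = "")
  invisible(x)
}

#' @exportS3Method base::print
print.two_layer_graph <- function(x, ...) {
  s <- graph_summary(x)
  cat("<two_layer_graph>\n",
      "  Number of tumor samples: ", s$n_tumors, "\n",
      "  Number of genes: ", s$n_genes, "\n",
      "  Number of hasGene relations: ", s$n_has_gene, "\n",
      "  Number of gene-gene interactions: ", s$n_interactions, "\n",
      "  Bipartite density: ", signif(s$bipartite_density, 4), "\n", sep = "")
  invisible(x)
}
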