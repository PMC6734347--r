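# Independent brute-force oracles used across the suite. They deliberately
# share no code with the package internals: sets and loops only.

# Neighborhood scores by explicit set enumeration on label pairs.
oracle_neighborhood <- function(pairs, tumor, gene, method) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  names(pairs) <- c("tumor", "gene")
  n_out <- function(t) unique(pairs$gene[pairs$tumor == t])
  n_in <- function(g) unique(pairs$tumor[pairs$gene == g])
  deg_gene <- function(g) length(n_in(g))
  nout_x <- n_out(tumor)
  nprime_y <- unique(unlist(lapply(n_in(gene), n_out)))
  z <- intersect(nout_x, nprime_y)
  switch(method,
    common_neighbors = length(z),
    jaccard = {
      u <- union(nout_x, nprime_y)
      if (length(u) == 0) 0 else length(z) / length(u)
    },
    preferential_attachment = length(nout_x) * length(nprime_y),
    adamic_adar = sum(vapply(z, function(g) {
      d <- deg_gene(g)
      if (d > 1) 1 / log(d) else 0
    }, 0)),
    resource_allocation = sum(vapply(z, function(g) 1 / deg_gene(g), 0)),
    stop("unknown method")
  )
}

# Depth-limited walk enumeration on the combined two-layer graph.
oracle_katz <- function(graph, tumor, gene, beta, max_len) {
  nT <- length(graph$layer1$tumors)
  nG <- length(graph$layer1$genes)
  adj <- vector("list", nT + nG)
  for (r in seq_len(nrow(graph$layer1$edges))) {
    t <- graph$layer1$edges[r, 1]
    g <- nT + graph$layer1$edges[r, 2]
    adj[[t]] <- c(adj[[t]], g)              # directed tumor -> gene
  }
  for (r in seq_len(nrow(graph$layer2$edges))) {
    a <- nT + graph$layer2$edges[r, 1]
    b <- nT + graph$layer2$edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  target <- nT + match(toupper(gene), graph$layer1$genes)
  counts <- integer(max_len)
  walk <- function(node, len) {
    if (len > 0 && node == target) counts[len] <<- counts[len] + 1L
    if (len == max_len) return(invisible())
    for (nxt in adj[[node]]) walk(nxt, len + 1L)
  }
  walk(match(tumor, graph$layer1$tumors), 0L)
  sum(beta^seq_len(max_len) * counts)
}

# Dense linear solve of the restart walk on layer 2 (dangling mass returns
# to the restart vector).
oracle_ppr <- function(graph, tumor, restart, train_edges = graph$layer1$edges) {
  n <- length(graph$layer1$genes)
  W <- as.matrix(interaction_adjacency(graph$layer2, weighted = TRUE))
  d <- colSums(W)
  P <- sweep(W, 2, ifelse(d > 0, d, 1), "/")
  P[, d == 0] <- 0
  ti <- match(tumor, graph$layer1$tumors)
  s <- numeric(n)
  s[train_edges[train_edges[, 1] == ti, 2]] <- 1
  s <- s / sum(s)
  Pd <- P + s %o% as.numeric(d == 0)       # dangling columns restart
  x <- solve(diag(n) - (1 - restart) * Pd, restart * s)
  names(x) <- graph$layer1$genes
  x
}

# Exhaustive (n' + 0.5 n'') / n comparison loop.
oracle_auc <- function(pos, neg) {
  n_higher <- 0
  n_equal <- 0
  for (p in pos) {
    for (q in neg) {
      if (p > q) n_higher <- n_higher + 1
      else if (p == q) n_equal <- n_equal + 1
    }
  }
  (n_higher + 0.5 * n_equal) / (length(pos) * length(neg))
}

# Group-by-maximum collapse of protein pairs onto gene pairs.
oracle_protein_collapse <- function(protein_edges, mapping) {
  g1 <- mapping$gene[match(protein_edges[[1]], mapping$protein)]
  g2 <- mapping$gene[match(protein_edges[[2]], mapping$protein)]
  w <- protein_edges[[3]]
  keep <- !is.na(g1) & !is.na(g2) & g1 != g2
  g1 <- toupper(g1[keep]); g2 <- toupper(g2[keep]); w <- w[keep]
  key <- paste(pmin(g1, g2), pmax(g1, g2), sep = "|")
  out <- tapply(w, key, max)
  out[order(names(out))]
}

# Random small two-layer graph for property tests.
random_graph <- function(n_tumors, n_genes, p_bip = 0.3, p_int = 0.3,
                         weighted = FALSE, seed = 1) {
  set.seed(seed)
  tumors <- sprintf("T%02d", seq_len(n_tumors))
  genes <- sprintf("G%02d", seq_len(n_genes))
  bip <- expand.grid(tumor = tumors, gene = genes,
                     stringsAsFactors = FALSE)
  bip <- bip[runif(nrow(bip)) < p_bip, ]
  if (nrow(bip) == 0) bip <- data.frame(tumor = tumors[1], gene = genes[1])
  cmb <- t(combn(n_genes, 2))
  sel <- runif(nrow(cmb)) < p_int
  ie <- data.frame(gene1 = genes[cmb[sel, 1]], gene2 = genes[cmb[sel, 2]])
  if (nrow(ie) == 0) ie <- data.frame(gene1 = genes[1], gene2 = genes[2])
  w <- if (weighted) runif(nrow(ie), 0.1, 1) else NULL
  two_layer_graph(
    bipartite_layer(bip, tumors = tumors, genes = genes),
    interaction_layer(ie, weights = w, genes = genes)
  )
}
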