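#' Baseline method specification
#'
#' Holds the comparison method and its parameters: the five bipartite
#' neighborhood scores, truncated Katz, personalized PageRank (PPR), and the
#' uniform-random benchmark.
#'
#' @param method one of `"common_neighbors"` (`"cn"`), `"jaccard"` (`"js"`),
#'   `"adamic_adar"` (`"aa"`), `"preferential_attachment"` (`"pa"`),
#'   `"resource_allocation"` (`"ra"`), `"katz"`, `"ppr"`, `"random"`.
#' @param katz_beta path-damping factor beta > 0 (default 1e-4).
#' @param katz_max_length truncation length L >= 1 for Katz (default 5).
#' @param ppr_restart restart probability in (0, 1\] (default 0.15).
#' @param seed integer seed for the random baseline (default 1).
#' @return an object of class `baseline_spec`.
#' @export
baseline_spec <- function(method, katz_beta = 1e-4, katz_max_length = 5L,
                          ppr_restart = 0.15, seed = 1L) {
  method <- .canonical_method(method)
  .assert(is.numeric(katz_beta) && katz_beta > 0, "katz_beta must be > 0")
  katz_max_length <- as.integer(katz_max_length)
  .assert(katz_max_length >= 1, "katz_max_length must be >= 1")
  .assert(is.numeric(ppr_restart) && ppr_restart > 0 && ppr_restart <= 1,
          "ppr_restart must lie in (0, 1]")
  structure(
    list(method = method, katz_beta = katz_beta,
         katz_max_length = katz_max_length, ppr_restart = ppr_restart,
         seed = as.integer(seed)),
    class = "baseline_spec"
  )
}

.method_aliases <- c(
  cn = "common_neighbors", common_neighbors = "common_neighbors",
  js = "jaccard", jaccard = "jaccard",
  aa = "adamic_adar", adamic_adar = "adamic_adar", aai = "adamic_adar",
  pa = "preferential_attachment", preferential_attachment = "preferential_attachment",
  ra = "resource_allocation", resource_allocation = "resource_allocation",
  katz = "katz", ppr = "ppr", random = "random", heat = "heat", hd = "heat"
)

.canonical_method <- function(method) {
  m <- .method_aliases[tolower(method)]
  .assert(!is.na(m), "unknown method '", method, "'; valid methods: ",
          paste(sort(unique(.method_aliases)), collapse = ", "))
  unname(m)
}

.neighborhood_methods <- c("common_neighbors", "jaccard", "adamic_adar",
                           "preferential_attachment", "resource_allocation")

## All-pairs neighborhood scores via sparse products.
##
## z-set(x, y) = N_out(x) intersect N'(y), where N'(y) is the union of the
## gene sets of the tumors linked to y (so z is in N'(y) iff some tumor links
## both y and z). With B the train bipartite 0/1 matrix and P the 0/1
## gene co-occurrence pattern (t(B) B > 0), common neighbors is B P, and
## Adamic/Adar and resource allocation reweight the z rows of P by
## 1/log(deg z) and 1/deg z, deg z being z's bipartite (tumor) degree.
.neighborhood_matrix <- function(layer1, method, train_edges = layer1$edges) {
  B <- bipartite_adjacency(layer1, train_edges)
  P <- Matrix::crossprod(B)        # gene x gene co-occurrence counts
  P@x <- rep(1, length(P@x))       # pattern only
  outdeg <- Matrix::rowSums(B)     # |N_out(tumor)|
  degg <- Matrix::colSums(B)       # bipartite gene degree
  nprime <- Matrix::colSums(P)     # |N'(gene)|
  S <- switch(method,
    common_neighbors = B %*% P,
    jaccard = {
      CN <- as.matrix(B %*% P)
      denom <- outer(outdeg, nprime, "+") - CN
      out <- ifelse(denom > 0, CN / denom, 0)
      out
    },
    preferential_attachment = outer(outdeg, nprime),
    adamic_adar = {
      wz <- ifelse(degg > 1, 1 / log(degg), 0)  # deg <= 1 contributes 0
      B %*% (Matrix::Diagonal(x = wz) %*% P)
    },
    resource_allocation = {
      wz <- ifelse(degg >= 1, 1 / degg, 0)
      B %*% (Matrix::Diagonal(x = wz) %*% P)
    },
    stop("not a neighborhood method: ", method)
  )
  S <- as.matrix(S)
  dimnames(S) <- list(layer1$tumors, layer1$genes)
  S
}

#' Bipartite neighborhood similarity score
#'
#' Scores a candidate tumor-gene pair with one of the classical
#' neighborhood metrics adapted to the directed bipartite layer: the
#' tumor's gene set is compared with the union of gene sets of the tumors
#' linked to the candidate gene. Common-neighbor genes `z` are weighted by
#' `1/log(deg z)` (Adamic/Adar; genes with bipartite degree <= 1 contribute
#' 0) or `1/deg z` (resource allocation), where `deg z` is the number of
#' tumors linked to `z`.
#'
#' @param layer1 a [bipartite_layer].
#' @param tumor,gene labels of the candidate pair.
#' @param method one of the five neighborhood methods (see [baseline_spec]).
#' @param train_edges integer edge matrix of known links (default: all).
#' @return a single numeric score.
#' @export
neighborhood_score <- function(layer1, tumor, gene, method,
                               train_edges = layer1$edges) {
  method <- .canonical_method(method)
  .assert(method %in% .neighborhood_methods,
          "not a neighborhood method: ", method)
  ti <- match(tumor, layer1$tumors)
  gi <- match(toupper(gene), layer1$genes)
  .assert(!is.na(ti), "unknown tumor: ", tumor)
  .assert(!is.na(gi), "unknown gene: ", gene)
  S <- .neighborhood_matrix(layer1, method, train_edges)
  S[ti, gi]
}

## Combined two-layer adjacency for path counting: block matrix over
## (tumors, genes) with directed tumor->gene train edges and symmetric
## gene-gene edges.
.combined_adjacency <- function(graph, train_edges) {
  nT <- length(graph$layer1$tumors)
  nG <- length(graph$layer1$genes)
  e1 <- train_edges
  e2 <- graph$layer2$edges
  Matrix::sparseMatrix(
    i = c(e1[, 1], nT + e2[, 1], nT + e2[, 2]),
    j = c(nT + e1[, 2], nT + e2[, 2], nT + e2[, 1]),
    x = 1, dims = c(nT + nG, nT + nG)
  )
}

## Truncated Katz scores for the tumors at positions `ti`: walk counts of
## length 1..L accumulated via sparse row-vector products.
.katz_matrix <- function(graph, ti, train_edges, spec) {
  nT <- length(graph$layer1$tumors)
  nG <- length(graph$layer1$genes)
  A <- .combined_adjacency(graph, train_edges)
  S <- Matrix::sparseMatrix(i = seq_along(ti), j = ti, x = 1,
                            dims = c(length(ti), nT + nG))
  acc <- matrix(0, length(ti), nG)
  for (l in seq_len(spec$katz_max_length)) {
    S <- S %*% A
    acc <- acc + spec$katz_beta^l * as.matrix(S[, nT + seq_len(nG), drop = FALSE])
  }
  dimnames(acc) <- list(graph$layer1$tumors[ti], graph$layer1$genes)
  acc
}

#' Truncated Katz score
#'
#' Sum over path lengths `l = 1..L` of `beta^l` times the number of walks of
#' length `l` from the tumor to the gene on the combined two-layer graph
#' (directed tumor-to-gene training edges plus the undirected interaction
#' edges).
#'
#' @param graph a [two_layer_graph].
#' @param tumor,gene labels of the candidate pair.
#' @param spec a [baseline_spec] carrying `katz_beta` and `katz_max_length`.
#' @param train_edges integer edge matrix of known links (default: all).
#' @return a single numeric score.
#' @export
katz_score <- function(graph, tumor, gene, spec = baseline_spec("katz"),
                       train_edges = graph$layer1$edges) {
  ti <- match(tumor, graph$layer1$tumors)
  gi <- match(toupper(gene), graph$layer1$genes)
  .assert(!is.na(ti), "unknown tumor: ", tumor)
  .assert(!is.na(gi), "unknown gene: ", gene)
  .assert(spec$katz_beta > 0, "katz_beta must be > 0")
  .katz_matrix(graph, ti, train_edges, spec)[1, gi]
}

## PPR stationary vectors for tumors at positions `ti`; returns genes x
## tumors. Walk on the interaction layer with restart at the tumor's seed
## genes; dangling genes redistribute their mass to the restart vector.
.ppr_matrix <- function(graph, ti, train_edges, spec,
                        tol = 1e-8, max_iter = 1000) {
  n <- length(graph$layer1$genes)
  W <- interaction_adjacency(graph$layer2, weighted = TRUE)
  d <- Matrix::colSums(W)
  P <- W %*% Matrix::Diagonal(x = ifelse(d > 0, 1 / d, 0))
  dangling <- d == 0
  sel <- train_edges[train_edges[, 1] %in% ti, , drop = FALSE]
  S <- matrix(0, n, length(ti))
  S[cbind(sel[, 2], match(sel[, 1], ti))] <- 1
  tot <- colSums(S)
  if (any(tot == 0)) {
    warning(sum(tot == 0),
            " tumor(s) with no seed genes: uniform restart used")
    S[, tot == 0] <- 1
    tot[tot == 0] <- n
  }
  S <- sweep(S, 2, tot, "/")
  r <- spec$ppr_restart
  X <- S
  for (iter in seq_len(max_iter)) {
    dmass <- colSums(X[dangling, , drop = FALSE])
    Xn <- (1 - r) * (as.matrix(P %*% X) + sweep(S, 2, dmass, "*")) + r * S
    delta <- max(abs(Xn - X))
    X <- Xn
    if (delta < tol) break
  }
  rownames(X) <- graph$layer1$genes
  X
}

#' Personalized PageRank gene scores for a tumor
#'
#' Stationary distribution of a random walk on the interaction layer that,
#' with probability `ppr_restart` at each step, returns to the tumor's
#' (training) seed genes, chosen uniformly; otherwise it moves to a random
#' neighbor (weight-proportionally on weighted layers). Dangling genes pass
#' their mass back to the restart distribution, so the result sums to 1.
#'
#' @param graph a [two_layer_graph].
#' @param tumor tumor label.
#' @param spec a [baseline_spec] carrying `ppr_restart`.
#' @param train_edges integer edge matrix of known links (default: all).
#' @return named numeric vector of stationary probabilities over genes.
#' @export
ppr_score <- function(graph, tumor, spec = baseline_spec("ppr"),
                      train_edges = graph$layer1$edges) {
  ti <- match(tumor, graph$layer1$tumors)
  .assert(!is.na(ti), "unknown tumor: ", tumor)
  drop(.ppr_matrix(graph, ti, train_edges, spec)[, 1])
}

#' Uniform-random benchmark scores
#'
#' Assigns each candidate pair an i.i.d. uniform(0, 1) score, reproducible
#' under `seed`. The benchmark every informative method must beat.
#'
#' @param candidates data frame with columns `tumor`, `gene`.
#' @param seed integer seed.
#' @return a `score_table` with per-tumor dense ranks.
#' @export
random_score <- function(candidates, seed = 1L) {
  candidates <- as.data.frame(candidates, stringsAsFactors = FALSE)
  set.seed(as.integer(seed))
  df <- data.frame(
    tumor = as.character(candidates[[1]]),
    gene = toupper(as.character(candidates[[2]])),
    score = stats::runif(nrow(candidates))
  )
  parts <- split(seq_len(nrow(df)), df$tumor)
  out <- do.call(rbind, lapply(parts, function(idx) {
    d <- df[idx, ]
    d <- d[order(-d$score, d$gene), ]
    d$rank <- .dense_rank_desc(d$score)
    d
  }))
  rownames(out) <- NULL
  structure(out, class = c("score_table", "data.frame"), method = "random")
}

## Unified all-pairs scorer used by evaluation and the permutation test:
## returns a |ti| x n_genes matrix of scores under `method`.
.score_matrix <- function(graph, method, ti, train_edges,
                          params = diffusion_params(),
                          spec = baseline_spec("random"),
                          degree_normalized = TRUE) {
  method <- .canonical_method(method)
  if (method == "heat") {
    S <- t(.diffuse_all(graph, ti, train_edges, params, degree_normalized))
    dimnames(S) <- list(graph$layer1$tumors[ti], graph$layer1$genes)
    return(S)
  }
  if (method %in% .neighborhood_methods) {
    return(.neighborhood_matrix(graph$layer1, method,
                                train_edges)[ti, , drop = FALSE])
  }
  if (method == "katz") return(.katz_matrix(graph, ti, train_edges, spec))
  if (method == "ppr") {
    S <- t(.ppr_matrix(graph, ti, train_edges, spec))
    rownames(S) <- graph$layer1$tumors[ti]
    return(S)
  }
  if (method == "random") {
    set.seed(spec$seed)
    S <- matrix(stats::runif(length(ti) * length(graph$layer1$genes)),
                nrow = length(ti))
    dimnames(S) <- list(graph$layer1$tumors[ti], graph$layer1$genes)
    return(S)
  }
  stop("unhandled method: ", method)
}
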