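#' Diffusion parameters
#'
#' Bundles the tunable knobs of the heat-diffusion model: thermal
#' conductivity `alpha` (0 = no diffusion), discrete iteration count `M`
#' (how far heat travels), non-jump probability `gamma` for the
#' PageRank-style teleport term, and output handling flags.
#'
#' @param alpha thermal conductivity, >= 0. Default 1.
#' @param M number of discrete iterations, integer >= 1. Default 6.
#' @param gamma probability of *not* taking a random jump, in \[0, 1\].
#'   Default 0.85.
#' @param teleport add the uniform random-jump term? Default `TRUE`.
#' @param normalize_output divide each tumor's heat vector by its sum?
#'   Default `TRUE` (does not change within-tumor ranking).
#' @param weighted_degree use weighted degree (strength) instead of the
#'   incident-edge count in the degree-normalized heat matrix. Default
#'   `FALSE`.
#' @return an object of class `diffusion_params`.
#' @export
diffusion_params <- function(alpha = 1, M = 6L, gamma = 0.85,
                             teleport = TRUE, normalize_output = TRUE,
                             weighted_degree = FALSE) {
  .assert(is.numeric(alpha) && length(alpha) == 1 && alpha >= 0,
          "alpha must be a single number >= 0")
  M <- as.integer(M)
  .assert(length(M) == 1 && !is.na(M) && M >= 1, "M must be an integer >= 1")
  .assert(is.numeric(gamma) && length(gamma) == 1 && gamma >= 0 && gamma <= 1,
          "gamma must lie in [0, 1]")
  structure(
    list(alpha = alpha, M = M, gamma = gamma,
         teleport = isTRUE(teleport),
         normalize_output = isTRUE(normalize_output),
         weighted_degree = isTRUE(weighted_degree)),
    class = "diffusion_params"
  )
}

.new_heat_matrix <- function(mat, variant, gamma = NA_real_) {
  structure(
    list(mat = mat, variant = variant, gamma = gamma, n = nrow(mat)),
    class = "heat_matrix"
  )
}

#' Heat matrix of an unweighted interaction graph
#'
#' Laplacian-style operator for heat flow on the undirected, unweighted
#' gene graph: off-diagonal entry (i, j) is 1 for every interaction edge,
#' diagonal entry i is minus the degree of gene i. Every column sums to
#' zero, so total heat is conserved under diffusion.
#'
#' @param layer2 an [interaction_layer] (weights, if any, are ignored).
#' @return an object of class `heat_matrix` (`variant = "unweighted"`)
#'   wrapping a sparse symmetric matrix.
#' @export
build_heat_matrix_unweighted <- function(layer2) {
  .assert(inherits(layer2, "interaction_layer"), "need an interaction_layer")
  A <- interaction_adjacency(layer2, weighted = FALSE)
  deg <- Matrix::colSums(A)
  .new_heat_matrix(A - Matrix::Diagonal(x = deg), "unweighted")
}

#' Degree-normalized heat matrix of a weighted interaction graph
#'
#' Operator for heat flow on the undirected weighted gene graph with
#' sender-degree normalization: gene j passes `w_ji / d_j` of its heat to
#' neighbor i, where `d_j` is j's incident-edge count, and loses
#' `(tau_j / d_j) * sum_k w_jk` in total (`tau_j = 0` for isolated genes,
#' which therefore retain their heat). The normalization gives every gene
#' unit influence regardless of its degree, removing the high-degree bias
#' of the unweighted operator. Columns sum to zero.
#'
#' @param layer2 an [interaction_layer]; layers without stored weights use
#'   implicit weight 1.
#' @param weighted_degree normalize by weighted degree (strength) instead of
#'   the incident-edge count. Default `FALSE`.
#' @return a `heat_matrix` (`variant = "weighted"`).
#' @export
build_heat_matrix_weighted <- function(layer2, weighted_degree = FALSE) {
  .assert(inherits(layer2, "interaction_layer"), "need an interaction_layer")
  W <- interaction_adjacency(layer2, weighted = TRUE)
  d <- if (weighted_degree) Matrix::colSums(W)
       else Matrix::colSums(interaction_adjacency(layer2, weighted = FALSE))
  strength <- Matrix::colSums(W)
  inv_d <- ifelse(d > 0, 1 / d, 0)
  ## off-diagonal (i, j) = w_ij / d_j  (W is symmetric, so w_ji = w_ij)
  H <- W %*% Matrix::Diagonal(x = inv_d)
  diag_vals <- ifelse(d > 0, strength * inv_d, 0)  # tau = 0 for isolated genes
  H <- H - Matrix::Diagonal(x = diag_vals)
  dimnames(H) <- dimnames(W)
  .new_heat_matrix(H, "weighted")
}

#' Wrap a matrix as a heat-matrix object
#'
#' Builds a `heat_matrix` from an explicitly given operator, e.g. a literal
#' fixture such as [toy_printed_heat_matrix()]. No column-sum validation is
#' applied -- the caller vouches for the operator.
#'
#' @param mat square numeric matrix (dense or sparse).
#' @param variant `"unweighted"`, `"weighted"` or `"teleport"`.
#' @param gamma non-jump probability (teleport variant only).
#' @return a `heat_matrix`.
#' @export
as_heat_matrix <- function(mat, variant = c("unweighted", "weighted",
                                            "teleport"),
                           gamma = NA_real_) {
  variant <- match.arg(variant)
  .assert(nrow(mat) == ncol(mat), "heat matrix must be square")
  .assert(variant != "teleport" || (gamma >= 0 && gamma <= 1),
          "teleport variant needs gamma in [0, 1]")
  .new_heat_matrix(Matrix::Matrix(mat, sparse = TRUE), variant, gamma)
}

#' Add the teleport (random-jump) term
#'
#' Augments a heat matrix with a uniform random-interaction term:
#' `R = gamma * H + (1 - gamma) * g %*% t(1)` with `g = (1/n) * 1`. The
#' dense rank-1 term is never materialized; matrix-vector products apply it
#' implicitly, so only the sparse part is stored. With teleport, every
#' column of `R` sums to `1 - gamma`.
#'
#' @param H a `heat_matrix` of variant `"unweighted"` or `"weighted"`.
#' @param gamma non-jump probability in \[0, 1\]; `gamma = 1` leaves `H`
#'   unchanged, `gamma = 0` is pure teleport.
#' @return a `heat_matrix` of variant `"teleport"`.
#' @export
add_teleport <- function(H, gamma = 0.85) {
  .assert(inherits(H, "heat_matrix"), "need a heat_matrix")
  .assert(H$variant %in% c("unweighted", "weighted"),
          "teleport is added on top of a plain heat matrix")
  .assert(is.numeric(gamma) && length(gamma) == 1 && gamma >= 0 && gamma <= 1,
          "gamma must lie in [0, 1]")
  .assert(H$n >= 1, "teleport needs at least one gene")
  .new_heat_matrix(H$mat, "teleport", gamma = gamma)
}

## Apply the heat operator to a vector or a column matrix, honoring the
## implicit rank-1 teleport term.
.heat_apply <- function(H, x) {
  base <- H$mat %*% x
  if (H$variant != "teleport") return(base)
  g <- H$gamma
  if (is.matrix(x) || inherits(x, "Matrix")) {
    jump <- matrix(rep(Matrix::colSums(x), each = H$n), nrow = H$n)
  } else {
    jump <- sum(x)
  }
  g * base + ((1 - g) / H$n) * jump
}

## Dense realization of the operator (small graphs / oracle use only).
.heat_dense <- function(H) {
  R <- as.matrix(H$mat)
  if (H$variant == "teleport") {
    R <- H$gamma * R + (1 - H$gamma) / H$n
  }
  R
}

#' Initial heat (seed) vector for a tumor
#'
#' Binary indicator over genes: 1 where the tumor has a (training) hasGene
#' edge, 0 elsewhere. This is the heat source for that tumor's diffusion.
#'
#' @param graph a [two_layer_graph].
#' @param tumor tumor label.
#' @param train_edges integer edge matrix (subset of `graph$layer1$edges`);
#'   defaults to all observed edges.
#' @return a named numeric vector over genes.
#' @export
seed_vector <- function(graph, tumor, train_edges = graph$layer1$edges) {
  .assert(inherits(graph, "two_layer_graph"), "need a two_layer_graph")
  ti <- match(tumor, graph$layer1$tumors)
  .assert(!is.na(ti), "unknown tumor: ", tumor)
  f0 <- numeric(length(graph$layer1$genes))
  names(f0) <- graph$layer1$genes
  f0[train_edges[train_edges[, 1] == ti, 2]] <- 1
  f0
}

#' Exact heat diffusion via the matrix exponential
#'
#' Computes `f(1) = expm(alpha * R) %*% f0` with a dense matrix
#' exponential. Intended as the small-graph reference; refuses graphs larger
#' than `max_n` nodes (use [diffuse_discrete()] there).
#'
#' @param H a `heat_matrix` (any variant).
#' @param f0 initial heat vector (length `H$n`).
#' @param alpha thermal conductivity; `alpha = 0` returns `f0` exactly.
#' @param max_n dense-computation cap (default 2000).
#' @return the diffused heat vector.
#' @export
diffuse_exact <- function(H, f0, alpha = 1, max_n = 2000) {
  .assert(inherits(H, "heat_matrix"), "need a heat_matrix")
  .assert(H$n <= max_n,
          "graph too large for the dense matrix exponential (n = ", H$n,
          " > ", max_n, "); use diffuse_discrete()")
  .assert(length(f0) == H$n, "f0 must have one entry per gene")
  .assert(is.numeric(alpha) && alpha >= 0, "alpha must be >= 0")
  R <- Matrix::Matrix(.heat_dense(H))
  out <- as.numeric(Matrix::expm(alpha * R) %*% f0)
  names(out) <- rownames(H$mat)
  out
}

#' Discrete heat diffusion (linear-cost approximation)
#'
#' Computes `f(1) = (I + (alpha/M) R)^M f0` as `M` sparse matrix-vector
#' applications, never materializing a matrix power: cost `O(M |E|)` per
#' seed vector. Converges to the matrix exponential as `M` grows.
#'
#' @param H a `heat_matrix` (any variant).
#' @param f0 initial heat vector (length `H$n`), or a matrix with one seed
#'   column per tumor.
#' @param params a [diffusion_params] (uses `alpha` and `M`).
#' @return diffused vector (or matrix, matching `f0`).
#' @export
diffuse_discrete <- function(H, f0, params = diffusion_params()) {
  .assert(inherits(H, "heat_matrix"), "need a heat_matrix")
  .assert(inherits(params, "diffusion_params"), "need diffusion_params")
  is_vec <- is.null(dim(f0))
  f <- f0
  step <- params$alpha / params$M
  for (m in seq_len(params$M)) {
    f <- f + step * .heat_apply(H, f)
  }
  if (is_vec) {
    f <- as.numeric(f)
    names(f) <- rownames(H$mat)
  } else {
    f <- as.matrix(f)
    rownames(f) <- rownames(H$mat)
  }
  f
}

#' Normalize a heat vector to unit sum
#'
#' Divides every entry by the vector total so the result sums to 1. A
#' zero-sum vector (a tumor whose every edge was held out, diffused without
#' teleport) is returned unchanged with a warning.
#'
#' @param f numeric heat vector.
#' @return normalized vector.
#' @export
normalize_heat <- function(f) {
  s <- sum(f)
  if (s == 0) {
    warning("heat vector sums to zero; returned unchanged")
    return(f)
  }
  f / s
}

#' Score candidate tumor-gene links by heat diffusion
#'
#' Builds the heat matrix once, seeds one binary vector per tumor from the
#' training edges, runs the discrete diffusion for all tumors at once, and
#' ranks every candidate (tumor, gene) pair not in the training set by its
#' diffused heat. Ties in the per-tumor ranking are broken by gene label so
#' output is deterministic.
#'
#' @param graph a [two_layer_graph].
#' @param tumors tumor labels to score (default: all).
#' @param train_edges integer edge matrix treated as known (default: all
#'   observed layer-1 edges).
#' @param params a [diffusion_params].
#' @param degree_normalized build the degree-normalized heat matrix
#'   ([build_heat_matrix_weighted()]; the default -- unweighted layers use
#'   implicit weight 1). `FALSE` selects the plain unweighted operator
#'   ([build_heat_matrix_unweighted()]), which is biased toward high-degree
#'   genes and is kept for the degree-bias contrast.
#' @return a `score_table` data frame with columns `tumor`, `gene`, `score`,
#'   `rank` (dense rank, 1 = best, per tumor), sorted by tumor then rank.
#' @export
score_tumors <- function(graph, tumors = graph$layer1$tumors,
                         train_edges = graph$layer1$edges,
                         params = diffusion_params(),
                         degree_normalized = TRUE) {
  .assert(inherits(graph, "two_layer_graph"), "need a two_layer_graph")
  if (length(tumors) == 0) {
    return(structure(
      data.frame(tumor = character(0), gene = character(0),
                 score = numeric(0), rank = integer(0)),
      class = c("score_table", "data.frame"), method = "heat"
    ))
  }
  ti <- match(tumors, graph$layer1$tumors)
  .assert(!anyNA(ti), "unknown tumor label(s): ",
          paste(tumors[is.na(ti)], collapse = ", "))
  F1 <- .diffuse_all(graph, ti, train_edges, params, degree_normalized)
  .score_table_from_matrix(graph, ti, train_edges, t(F1), method = "heat")
}

## Diffuse seeds for the tumors at positions `ti`; returns genes x tumors.
.diffuse_all <- function(graph, ti, train_edges, params, degree_normalized) {
  H <- if (degree_normalized) {
    build_heat_matrix_weighted(graph$layer2,
                               weighted_degree = params$weighted_degree)
  } else {
    build_heat_matrix_unweighted(graph$layer2)
  }
  if (params$teleport) H <- add_teleport(H, params$gamma)
  n <- length(graph$layer1$genes)
  sel <- train_edges[train_edges[, 1] %in% ti, , drop = FALSE]
  F0 <- Matrix::sparseMatrix(
    i = sel[, 2], j = match(sel[, 1], ti), x = 1,
    dims = c(n, length(ti))
  )
  F1 <- diffuse_discrete(H, F0, params)
  if (params$normalize_output) {
    tot <- colSums(F1)
    if (any(tot == 0)) {
      warning(sum(tot == 0), " tumor(s) with zero total heat left unnormalized")
    }
    F1 <- sweep(F1, 2, ifelse(tot == 0, 1, tot), "/")
  }
  F1
}

## Assemble the candidate score table from a tumors x genes score matrix.
.score_table_from_matrix <- function(graph, ti, train_edges, S, method) {
  n_genes <- length(graph$layer1$genes)
  train_keys <- .edge_keys(train_edges, n_genes)
  out <- vector("list", length(ti))
  for (k in seq_along(ti)) {
    t_pos <- ti[k]
    cand <- setdiff(seq_len(n_genes),
                    train_edges[train_edges[, 1] == t_pos, 2])
    if (length(cand) == 0) next
    sc <- as.numeric(S[k, cand])
    lab <- graph$layer1$genes[cand]
    ord <- order(-sc, lab)
    out[[k]] <- data.frame(
      tumor = graph$layer1$tumors[t_pos],
      gene = lab[ord],
      score = sc[ord],
      rank = .dense_rank_desc(sc[ord])
    )
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(res) <- NULL
  structure(res, class = c("score_table", "data.frame"), method = method)
}

#' Write a score table as delimited text
#'
#' Columns `tumor`, `gene`, `score`, `rank`; the scoring method is recorded
#' in a `#`-prefixed header comment line.
#'
#' @param scores a `score_table` (from [score_tumors()] or a baseline).
#' @param path output path.
#' @param top_k optional per-tumor truncation to the best `top_k` ranks.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path, top_k = NULL, sep = "\t") {
  df <- as.data.frame(scores)
  if (!is.null(top_k)) {
    df <- do.call(rbind, lapply(split(df, df$tumor),
                                function(d) d[d$rank <= top_k, ]))
    rownames(df) <- NULL
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# method: ", attr(scores, "method") %||% "unknown"), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
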