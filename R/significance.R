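#' Degree-preserving randomization of the interaction layer
#'
#' Double-edge-swap rewiring: repeatedly picks two edges (a, b) and (c, d)
#' and rewires them to (a, d), (c, b) (or (a, c), (b, d)), rejecting swaps
#' that would create self-loops or duplicate edges. Every node's degree is
#' preserved exactly; edge weights travel with the swapped stubs. `10 |E|`
#' swaps are attempted (rejected attempts count toward the budget).
#'
#' @param layer2 an [interaction_layer] with at least 2 edges (smaller
#'   layers are returned unchanged with a warning).
#' @param seed integer seed; the same seed reproduces the same rewiring.
#' @param n_attempts attempted swaps (default `10 * nrow(edges)`).
#' @return a rewired [interaction_layer] with the same degree sequence.
#' @export
randomize_interactions <- function(layer2, seed = 1L,
                                   n_attempts = 10L * nrow(layer2$edges)) {
  .assert(inherits(layer2, "interaction_layer"), "need an interaction_layer")
  m <- nrow(layer2$edges)
  if (m < 2) {
    warning("fewer than 2 interaction edges; layer returned unchanged")
    return(layer2)
  }
  set.seed(as.integer(seed))
  n <- length(layer2$genes)
  i <- layer2$edges[, 1]
  j <- layer2$edges[, 2]
  present <- new.env(hash = TRUE, parent = emptyenv())
  for (e in seq_len(m)) assign(as.character((i[e] - 1) * n + j[e]), TRUE, present)
  key <- function(a, b) as.character((min(a, b) - 1) * n + max(a, b))
  pick <- sample.int(m, n_attempts, replace = TRUE)
  pick2 <- sample.int(m, n_attempts, replace = TRUE)
  orient <- stats::runif(n_attempts) < 0.5
  for (t in seq_len(n_attempts)) {
    e1 <- pick[t]; e2 <- pick2[t]
    if (e1 == e2) next
    a <- i[e1]; b <- j[e1]; c <- i[e2]; d <- j[e2]
    if (orient[t]) { tmp <- c; c <- d; d <- tmp }  # swap direction choice
    ## proposed: (a, d) and (c, b)
    if (a == d || c == b) next
    k1 <- key(a, d); k2 <- key(c, b)
    if (k1 == k2) next
    if (exists(k1, present, inherits = FALSE) ||
        exists(k2, present, inherits = FALSE)) next
    rm(list = c(key(a, b), key(c, d)), envir = present)
    assign(k1, TRUE, present)
    assign(k2, TRUE, present)
    i[e1] <- min(a, d); j[e1] <- max(a, d)
    i[e2] <- min(c, b); j[e2] <- max(c, b)
  }
  out <- layer2
  out$edges <- cbind(i = i, j = j)
  out
}

#' Degree-preserving randomization of the bipartite layer
#'
#' Double-edge swaps restricted to tumor-to-gene edges: (t1, g1), (t2, g2)
#' become (t1, g2), (t2, g1) when neither already exists. Both marginal
#' degree sequences (tumor degrees and gene degrees) are preserved exactly.
#'
#' @param layer1 a [bipartite_layer] with at least 2 edges.
#' @param seed integer seed.
#' @param n_attempts attempted swaps (default `10 * nrow(edges)`).
#' @return a rewired [bipartite_layer].
#' @export
randomize_bipartite <- function(layer1, seed = 1L,
                                n_attempts = 10L * nrow(layer1$edges)) {
  .assert(inherits(layer1, "bipartite_layer"), "need a bipartite_layer")
  m <- nrow(layer1$edges)
  if (m < 2) {
    warning("fewer than 2 bipartite edges; layer returned unchanged")
    return(layer1)
  }
  set.seed(as.integer(seed))
  nG <- length(layer1$genes)
  ti <- layer1$edges[, 1]
  gi <- layer1$edges[, 2]
  present <- new.env(hash = TRUE, parent = emptyenv())
  for (e in seq_len(m)) assign(as.character((ti[e] - 1) * nG + gi[e]), TRUE, present)
  key <- function(t, g) as.character((t - 1) * nG + g)
  pick <- sample.int(m, n_attempts, replace = TRUE)
  pick2 <- sample.int(m, n_attempts, replace = TRUE)
  for (t in seq_len(n_attempts)) {
    e1 <- pick[t]; e2 <- pick2[t]
    if (e1 == e2) next
    t1 <- ti[e1]; g1 <- gi[e1]; t2 <- ti[e2]; g2 <- gi[e2]
    if (g1 == g2 || t1 == t2) next
    k1 <- key(t1, g2); k2 <- key(t2, g1)
    if (exists(k1, present, inherits = FALSE) ||
        exists(k2, present, inherits = FALSE)) next
    rm(list = c(key(t1, g1), key(t2, g2)), envir = present)
    assign(k1, TRUE, present)
    assign(k2, TRUE, present)
    gi[e1] <- g2
    gi[e2] <- g1
  }
  out <- layer1
  out$edges <- cbind(tumor = ti, gene = gi)
  out
}

#' Bonferroni-corrected significance threshold
#'
#' The per-test threshold `alpha_star / m` controlling the family-wise
#' error rate over `m` tests.
#'
#' @param alpha_star family-wise significance level, in (0, 1\].
#' @param m number of tests, integer >= 1.
#' @return the corrected threshold.
#' @export
bonferroni_threshold <- function(alpha_star, m) {
  .assert(is.numeric(alpha_star) && alpha_star > 0 && alpha_star <= 1,
          "alpha_star must lie in (0, 1]")
  m <- as.integer(m)
  .assert(length(m) == 1 && !is.na(m) && m >= 1, "m must be an integer >= 1")
  alpha_star / m
}

## p-values from an observed score vector and an N x n_pairs matrix of
## null scores: Omega = #\{null > observed\} strictly (ties do not count),
## p = Omega / N.
.perm_pvalue_counts <- function(observed, null_scores) {
  null_scores <- as.matrix(null_scores)
  .assert(ncol(null_scores) == length(observed),
          "one null-score column per observed score required")
  omega <- colSums(sweep(null_scores, 2, observed, ">"))
  list(omega = as.integer(omega), p_value = omega / nrow(null_scores))
}

#' Permutation significance of predicted tumor-gene links
#'
#' Records the heat-diffusion score of each candidate pair on the real
#' graph, then re-scores the same pairs on `N` degree-preserving
#' randomizations of the chosen layer. The p-value of a pair is
#' `Omega / N`, where `Omega` counts randomizations whose score strictly
#' exceeds the observed one. Significance is called against the
#' Bonferroni-corrected threshold `alpha_star / N` (the correction over the
#' N repetitions of the test).
#'
#' @param graph a [two_layer_graph].
#' @param pairs data frame of candidate pairs (columns `tumor`, `gene`).
#' @param params a [diffusion_params].
#' @param N number of randomizations (>= 1; 1000 in production, smaller for
#'   desk-scale runs).
#' @param seed integer seed; randomization `r` uses `seed + r`.
#' @param target which layer to randomize: `"interactions"` (layer 2) or
#'   `"bipartite"` (layer 1).
#' @param alpha_star family-wise level for the Bonferroni call (default
#'   0.05).
#' @param degree_normalized use the degree-normalized heat matrix (default).
#' @return an object of class `permutation_result`: list with `pairs` data
#'   frame (`tumor`, `gene`, `score`, `omega`, `p_value`, `significant`),
#'   `N`, `corrected_alpha`, `n_significant`.
#' @export
permutation_pvalues <- function(graph, pairs, params = diffusion_params(),
                                N = 1000L, seed = 1L,
                                target = c("interactions", "bipartite"),
                                alpha_star = 0.05,
                                degree_normalized = TRUE) {
  target <- match.arg(target)
  N <- as.integer(N)
  .assert(length(N) == 1 && !is.na(N) && N >= 1, "N must be an integer >= 1")
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  tumor_lab <- as.character(pairs[[1]])
  gene_lab <- toupper(as.character(pairs[[2]]))
  ti_all <- match(tumor_lab, graph$layer1$tumors)
  gi_all <- match(gene_lab, graph$layer1$genes)
  .assert(!anyNA(ti_all) && !anyNA(gi_all), "unknown tumor or gene in pairs")
  ti <- sort(unique(ti_all))
  pick <- cbind(match(ti_all, ti), gi_all)

  score_pairs <- function(g) {
    S <- suppressWarnings(
      .score_matrix(g, "heat", ti, g$layer1$edges, params = params,
                    degree_normalized = degree_normalized)
    )
    S[pick]
  }
  observed <- score_pairs(graph)
  null_scores <- matrix(NA_real_, N, length(observed))
  for (r in seq_len(N)) {
    g_r <- graph
    if (target == "interactions") {
      g_r$layer2 <- randomize_interactions(graph$layer2,
                                           seed = as.integer(seed) + r)
    } else {
      g_r$layer1 <- randomize_bipartite(graph$layer1,
                                        seed = as.integer(seed) + r)
    }
    null_scores[r, ] <- score_pairs(g_r)
  }
  counts <- .perm_pvalue_counts(observed, null_scores)
  corrected <- bonferroni_threshold(alpha_star, N)
  df <- data.frame(
    tumor = tumor_lab, gene = gene_lab, score = observed,
    omega = counts$omega, p_value = counts$p_value,
    significant = as.integer(counts$p_value < corrected)
  )
  structure(
    list(pairs = df, N = N, corrected_alpha = corrected,
         n_significant = sum(df$significant)),
    class = "permutation_result"
  )
}

#' @exportS3Method base::print
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> N = ", x$N, ", corrected alpha = ",
      format(x$corrected_alpha), "\n  ", x$n_significant, " of ",
      nrow(x$pairs), " pairs significant after Bonferroni\n", sep = "")
  invisible(x)
}

#' Write a permutation result as delimited text
#'
#' Columns `tumor`, `gene`, `score`, `p_value`,
#' `significant_after_bonferroni` (0/1), plus a JSON summary with `N`, the
#' corrected threshold and the significant count.
#'
#' @param result a `permutation_result`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return the directory, invisibly.
#' @export
write_permutation_result <- function(result, dir, prefix = "permtest") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- result$pairs[, c("tumor", "gene", "score", "p_value")]
  df$significant_after_bonferroni <- result$pairs$significant
  utils::write.table(df, file.path(dir, paste0(prefix, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(N = result$N, corrected_alpha = result$corrected_alpha,
         n_significant = result$n_significant, n_pairs = nrow(result$pairs)),
    file.path(dir, paste0(prefix, "_summary.json")),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
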