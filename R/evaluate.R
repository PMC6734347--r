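#' k-fold edge-holdout splits
#'
#' Randomly permutes the observed layer-1 edges under `seed` and partitions
#' them into `k` near-equal disjoint parts; fold `i` uses part `i` as test
#' edges and the remaining edges as training edges. Train and test are
#' disjoint and their union is the full edge set.
#'
#' @param layer1 a [bipartite_layer].
#' @param k number of folds (>= 2, <= number of edges).
#' @param seed integer seed.
#' @return a list of `k` fold objects, each a list with `fold_id`,
#'   `train_edges`, `test_edges` (integer edge matrices) and `seed`.
#' @export
make_folds <- function(layer1, k = 10L, seed = 1L) {
  .assert(inherits(layer1, "bipartite_layer"), "need a bipartite_layer")
  k <- as.integer(k)
  m <- nrow(layer1$edges)
  .assert(k >= 2, "k must be >= 2")
  .assert(k <= m, "k = ", k, " exceeds the number of edges (", m, ")")
  set.seed(as.integer(seed))
  perm <- sample.int(m)
  fold_of <- rep(seq_len(k), length.out = m)[order(perm)]
  lapply(seq_len(k), function(i) {
    list(
      fold_id = i,
      train_edges = layer1$edges[fold_of != i, , drop = FALSE],
      test_edges = layer1$edges[fold_of == i, , drop = FALSE],
      seed = as.integer(seed)
    )
  })
}

#' Train/validation/test edge split
#'
#' Splits the observed edges into disjoint parts with the given proportions
#' (honored to within one edge), e.g. `c(0.6, 0.2, 0.2)` for parameter
#' selection on a training set with held-out validation and test sets.
#'
#' @param layer1 a [bipartite_layer].
#' @param props numeric proportions summing to 1.
#' @param seed integer seed.
#' @return a list of integer edge matrices, one per proportion.
#' @export
split_edges <- function(layer1, props = c(0.6, 0.2, 0.2), seed = 1L) {
  .assert(abs(sum(props) - 1) < 1e-8, "proportions must sum to 1")
  m <- nrow(layer1$edges)
  set.seed(as.integer(seed))
  perm <- sample.int(m)
  sizes <- diff(round(cumsum(c(0, props)) * m))
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  lapply(seq_along(props), function(i) {
    layer1$edges[perm[seq(starts[i], ends[i])], , drop = FALSE]
  })
}

#' Rank-comparison AUC-ROC for link prediction
#'
#' The probability that a randomly chosen missing link (held-out edge)
#' scores higher than a randomly chosen non-existent link, with half credit
#' for ties: `AUC = (n' + 0.5 n'') / n` over all missing-by-nonexistent
#' comparisons. Computed via the rank-statistic equivalence (midranks), not
#' an explicit O(n^2) loop.
#'
#' @param test_scores scores of the held-out (missing) links.
#' @param nonedge_scores scores of non-existent links.
#' @return AUC in \[0, 1\].
#' @export
auc_roc <- function(test_scores, nonedge_scores) {
  .assert(length(test_scores) > 0, "no test scores")
  .assert(length(nonedge_scores) > 0, "no non-edge scores")
  np <- length(test_scores)
  nn <- length(nonedge_scores)
  r <- rank(c(test_scores, nonedge_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve
#'
#' Pools the scores, ranks them in descending order (positives = missing
#' links), and integrates precision over recall with the standard step-wise
#' interpolation (average precision over the positive positions).
#'
#' @inheritParams auc_roc
#' @return AUC-PR in (0, 1\].
#' @export
auc_pr <- function(test_scores, nonedge_scores) {
  .assert(length(test_scores) > 0, "no test scores")
  .assert(length(nonedge_scores) > 0, "no non-edge scores")
  lab <- c(rep(1L, length(test_scores)), rep(0L, length(nonedge_scores)))
  sc <- c(test_scores, nonedge_scores)
  ord <- order(-sc)
  lab <- lab[ord]
  prec <- cumsum(lab) / seq_along(lab)
  sum(prec[lab == 1L]) / sum(lab)
}

#' Cross-validated evaluation of a link-prediction method
#'
#' For each fold: scores are fit on the training edges only, the held-out
#' test edges are the positives, and (tumor, gene) pairs outside the full
#' observed edge set are the negatives (optionally a uniform sample capped
#' at `max_nonedges`). Both AUC-ROC and AUC-PR are recorded per fold and
#' aggregated as mean and standard deviation.
#'
#' @param graph a [two_layer_graph].
#' @param method method name (`"heat"` or any [baseline_spec] method).
#' @param k number of folds (default 10).
#' @param seed integer seed driving the fold split (and non-edge sampling).
#' @param params a [diffusion_params] (heat only).
#' @param spec a [baseline_spec] (baselines only; its `method` field is
#'   overridden by `method`).
#' @param degree_normalized use the degree-normalized heat matrix (heat
#'   only; the default, and the recommended operator -- unweighted layers
#'   use implicit weight 1). `FALSE` selects the plain unweighted operator,
#'   provided for the degree-bias contrast.
#' @param max_nonedges cap on the sampled non-edge comparison set per fold
#'   (`Inf` = exhaustive, the default).
#' @return an object of class `eval_result`: list with `per_fold` data frame
#'   (`fold_id`, `auc_roc`, `auc_pr`), `mean_auc_roc`, `sd_auc_roc`,
#'   `mean_auc_pr`, `sd_auc_pr`, `method`, `k`, `seed`.
#' @export
evaluate_method <- function(graph, method = "heat", k = 10L, seed = 1L,
                            params = diffusion_params(),
                            spec = baseline_spec("random"),
                            degree_normalized = TRUE,
                            max_nonedges = Inf) {
  method <- .canonical_method(method)
  spec$method <- method
  folds <- make_folds(graph$layer1, k = k, seed = seed)
  nT <- length(graph$layer1$tumors)
  nG <- length(graph$layer1$genes)
  all_keys <- .edge_keys(graph$layer1$edges, nG)
  per_fold <- lapply(folds, function(fold) {
    ti <- sort(unique(graph$layer1$edges[, 1]))
    if (method == "random") {
      ## fold-specific stream so folds are independent draws
      spec$seed <- as.integer(seed) * 1000L + fold$fold_id
    }
    S <- suppressWarnings(
      .score_matrix(graph, method, ti, fold$train_edges,
                    params = params, spec = spec,
                    degree_normalized = degree_normalized)
    )
    row_of <- match(seq_len(nT), ti)
    pos <- S[cbind(row_of[fold$test_edges[, 1]], fold$test_edges[, 2])]
    ## negatives: all pairs outside the observed edge set U - E
    cand_keys <- setdiff(seq_len(nT * nG) - 0, all_keys)
    if (is.finite(max_nonedges) && length(cand_keys) > max_nonedges) {
      set.seed(as.integer(seed) * 1000L + fold$fold_id)
      cand_keys <- sample(cand_keys, max_nonedges)
    }
    nt <- ((cand_keys - 1) %/% nG) + 1
    ng <- ((cand_keys - 1) %% nG) + 1
    keep <- !is.na(row_of[nt])
    neg <- S[cbind(row_of[nt[keep]], ng[keep])]
    data.frame(
      fold_id = fold$fold_id,
      auc_roc = auc_roc(pos, neg),
      auc_pr = auc_pr(pos, neg)
    )
  })
  per_fold <- do.call(rbind, per_fold)
  structure(
    list(
      per_fold = per_fold,
      mean_auc_roc = mean(per_fold$auc_roc),
      sd_auc_roc = stats::sd(per_fold$auc_roc),
      mean_auc_pr = mean(per_fold$auc_pr),
      sd_auc_pr = stats::sd(per_fold$auc_pr),
      method = method, k = as.integer(k), seed = as.integer(seed)
    ),
    class = "eval_result"
  )
}

#' @exportS3Method base::print
print.eval_result <- function(x, ...) {
  cat("<eval_result> method = ", x$method, ", k = ", x$k, "\n",
      "  AUC-ROC: ", sprintf("%.4f", x$mean_auc_roc), " +/- ",
      sprintf("%.4f", x$sd_auc_roc), "\n",
      "  AUC-PR:  ", sprintf("%.4f", x$mean_auc_pr), " +/- ",
      sprintf("%.4f", x$sd_auc_pr), "\n", sep = "")
  invisible(x)
}

#' Sweep the diffusion parameters alpha and M
#'
#' Cross-validated mean AUC-ROC for every (alpha, M) grid point; the best
#' cell is recorded in the `best` attribute. The same seed gives the same
#' sweep table.
#'
#' @param graph a [two_layer_graph].
#' @param alphas numeric grid of thermal conductivities.
#' @param Ms integer grid of iteration counts.
#' @param k folds (default 10).
#' @param seed integer seed.
#' @param params template [diffusion_params] for the non-swept fields.
#' @param degree_normalized use the degree-normalized heat matrix (default).
#' @return data frame with columns `alpha`, `M`, `mean_auc_roc`,
#'   `sd_auc_roc`, plus attribute `best` (row with the top mean AUC-ROC).
#' @export
sweep_parameters <- function(graph, alphas = seq(0, 1, by = 0.1),
                             Ms = 6L, k = 10L, seed = 1L,
                             params = diffusion_params(),
                             degree_normalized = TRUE) {
  .assert(length(alphas) > 0 && length(Ms) > 0, "empty parameter grid")
  grid <- expand.grid(alpha = alphas, M = as.integer(Ms))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p$alpha <- grid$alpha[i]
    p$M <- grid$M[i]
    ev <- evaluate_method(graph, "heat", k = k, seed = seed, params = p,
                          degree_normalized = degree_normalized)
    data.frame(alpha = p$alpha, M = p$M,
               mean_auc_roc = ev$mean_auc_roc, sd_auc_roc = ev$sd_auc_roc)
  })
  out <- do.call(rbind, res)
  attr(out, "best") <- out[which.max(out$mean_auc_roc), ]
  out
}

#' Write an evaluation result to disk
#'
#' Per-fold metrics as delimited text plus a JSON summary (mean and sd of
#' both metrics, method, fold count, seed).
#'
#' @param result an `eval_result`.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return the directory, invisibly.
#' @export
write_eval_result <- function(result, dir, prefix = "eval") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(
    result$per_fold, file.path(dir, paste0(prefix, "_folds.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(
    list(method = result$method, k = result$k, seed = result$seed,
         mean_auc_roc = round(result$mean_auc_roc, 4),
         sd_auc_roc = round(result$sd_auc_roc, 4),
         mean_auc_pr = round(result$mean_auc_pr, 4),
         sd_auc_pr = round(result$sd_auc_pr, 4)),
    file.path(dir, paste0(prefix, "_summary.json")),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
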