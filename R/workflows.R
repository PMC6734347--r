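#' Run configuration
#'
#' Validated bundle of everything a run needs, fully serializable so any
#' output can be reproduced from its manifest alone.
#'
#' @param layer1 path to the tumor-gene edge list.
#' @param layer2 path to the gene-gene interaction edge list.
#' @param weighted does `layer2` carry a score column?
#' @param score_scale score divisor for `layer2` (see
#'   [load_interaction_edges()]).
#' @param alpha,iterations,gamma,teleport,normalize diffusion settings (see
#'   [diffusion_params()]; `iterations` is `M`).
#' @param method scoring method for evaluation runs (see [baseline_spec()];
#'   `"heat"` for diffusion).
#' @param folds cross-validation fold count.
#' @param n_perm permutation count for significance runs.
#' @param perm_target layer randomized in significance runs
#'   (`"interactions"` or `"bipartite"`).
#' @param alpha_star family-wise level for the Bonferroni call.
#' @param n_top number of top-scored candidate pairs carried into the
#'   permutation test.
#' @param top_k optional per-tumor truncation of written predictions.
#' @param seed integer seed for every random choice in the run.
#' @param out output directory.
#' @return an object of class `run_config`.
#' @export
run_config <- function(layer1 = NULL, layer2 = NULL, weighted = FALSE,
                       score_scale = NULL, alpha = 1, iterations = 6L,
                       gamma = 0.85, teleport = TRUE, normalize = TRUE,
                       method = "heat", folds = 10L, n_perm = 1000L,
                       perm_target = "interactions", alpha_star = 0.05,
                       n_top = 100L, top_k = NULL, seed = 1L, out = ".") {
  params <- diffusion_params(alpha = alpha, M = iterations, gamma = gamma,
                             teleport = teleport,
                             normalize_output = normalize)
  method <- .canonical_method(method)
  structure(
    list(layer1 = layer1, layer2 = layer2, weighted = isTRUE(weighted),
         score_scale = score_scale, params = params, method = method,
         folds = as.integer(folds), n_perm = as.integer(n_perm),
         perm_target = perm_target, alpha_star = alpha_star,
         n_top = as.integer(n_top), top_k = top_k,
         seed = as.integer(seed), out = out),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' @param path a `.yaml`/`.yml` or `.json` file whose keys match the
#'   [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    .assert(requireNamespace("yaml", quietly = TRUE),
            "the yaml package is needed for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, obj)
}

.load_graph_from_config <- function(config) {
  .assert(!is.null(config$layer1), "config$layer1 (edge-list path) required")
  .assert(!is.null(config$layer2), "config$layer2 (edge-list path) required")
  l1 <- load_bipartite_edges(config$layer1)
  scale <- config$score_scale %||% (if (config$weighted) 1000 else 1)
  l2 <- load_interaction_edges(config$layer2, weighted = config$weighted,
                               score_scale = scale)
  two_layer_graph(l1, l2)
}

.write_manifest <- function(config, dir, extra = list()) {
  cfg <- config
  cfg$params <- unclass(cfg$params)
  manifest <- c(
    list(package = "heatlink",
         version = as.character(utils::packageVersion("heatlink")),
         config = unclass(cfg)),
    extra
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}

#' Predict tumor-gene links and write ranked score tables
#'
#' Loads (or accepts) the two-layer graph, runs the discrete heat diffusion
#' with all observed edges as seeds, and writes per-tumor ranked candidate
#' predictions plus a manifest that reproduces the run.
#'
#' @param config a [run_config].
#' @param graph optional pre-built [two_layer_graph] (skips file loading).
#' @return the `score_table`, invisibly.
#' @export
run_predict <- function(config, graph = NULL) {
  .assert(inherits(config, "run_config"), "need a run_config")
  graph <- graph %||% .load_graph_from_config(config)
  s <- graph_summary(graph)
  message("graph: ", s$n_tumors, " tumors, ", s$n_genes, " genes, ",
          s$n_has_gene, " hasGene edges, ", s$n_interactions,
          " interactions")
  scores <- score_tumors(graph, params = config$params)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  write_score_table(scores, file.path(config$out, "predictions.tsv"),
                    top_k = config$top_k)
  .write_manifest(config, config$out,
                  extra = list(graph_summary = s, command = "predict"))
  invisible(scores)
}

#' Cross-validate a method and write the evaluation report
#'
#' @inheritParams run_predict
#' @return the `eval_result`, invisibly.
#' @export
run_evaluate <- function(config, graph = NULL) {
  .assert(inherits(config, "run_config"), "need a run_config")
  graph <- graph %||% .load_graph_from_config(config)
  s <- graph_summary(graph)
  message("graph: ", s$n_tumors, " tumors, ", s$n_genes, " genes, ",
          s$n_has_gene, " hasGene edges, ", s$n_interactions,
          " interactions")
  result <- evaluate_method(
    graph, method = config$method, k = config$folds, seed = config$seed,
    params = config$params, spec = baseline_spec("random", seed = config$seed)
  )
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  write_eval_result(result, config$out)
  .write_manifest(config, config$out,
                  extra = list(graph_summary = s, command = "evaluate"))
  invisible(result)
}

#' Permutation-test the top predictions and write the report
#'
#' Scores every candidate pair, keeps the `n_top` best by heat score, and
#' runs the degree-preserving permutation test on them, including the
#' Bonferroni-corrected threshold in the summary.
#'
#' @inheritParams run_predict
#' @return the `permutation_result`, invisibly.
#' @export
run_permtest <- function(config, graph = NULL) {
  .assert(inherits(config, "run_config"), "need a run_config")
  graph <- graph %||% .load_graph_from_config(config)
  scores <- score_tumors(graph, params = config$params)
  top <- scores[order(-scores$score), c("tumor", "gene")]
  top <- utils::head(top, config$n_top)
  result <- permutation_pvalues(
    graph, top, params = config$params, N = config$n_perm,
    seed = config$seed, target = config$perm_target,
    alpha_star = config$alpha_star
  )
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  write_permutation_result(result, config$out)
  .write_manifest(config, config$out,
                  extra = list(command = "permtest"))
  invisible(result)
}
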