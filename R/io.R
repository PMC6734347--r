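#' Read a tumor-gene edge list
#'
#' Reads a delimited text file (tab, comma, or whitespace; optionally
#' gzipped) of `tumor_id, gene_symbol` rows into a [bipartite_layer]. A
#' header row is auto-detected by keyword. Duplicate rows are collapsed and
#' the resulting counts are reported via `message()`.
#'
#' @param path path to the edge-list file.
#' @return a [bipartite_layer].
#' @export
load_bipartite_edges <- function(path) {
  lines <- .read_lines_any(path)
  lines <- lines[nzchar(trimws(lines))]
  .assert(length(lines) > 0, "empty bipartite edge file: ", path)
  delim <- .sniff_delim(lines)
  fields <- lapply(lines, .split_fields, delim = delim)
  start <- if (.looks_like_header(fields[[1]])) 2L else 1L
  .assert(length(fields) >= start, "no data rows in bipartite edge file: ", path)
  bad <- which(vapply(fields, length, 1L)[seq(start, length(fields))] < 2)
  .assert(length(bad) == 0,
          "malformed bipartite edge row at line ", start - 1 + bad[1],
          " of ", path)
  rows <- fields[seq(start, length(fields))]
  layer <- bipartite_layer(data.frame(
    tumor = vapply(rows, `[`, "", 1),
    gene = vapply(rows, `[`, "", 2)
  ))
  message("loaded ", nrow(layer$edges), " hasGene edges (",
          length(layer$tumors), " tumors, ", length(layer$genes),
          " genes) from ", path)
  layer
}

#' Read a gene-gene interaction edge list
#'
#' Reads `gene1, gene2[, score]` rows into an [interaction_layer]. Scores
#' are divided by `score_scale` to land in (0, 1] -- STRING-style integer
#' scores use the default scale of 1000; already-normalized scores use 1.
#' Self-loops are dropped and duplicate pairs keep the maximum weight.
#'
#' @param path path to the edge-list file (tab/comma/whitespace delimited,
#'   optionally gzipped).
#' @param weighted does the file carry a third score column?
#' @param score_scale positive divisor applied to raw scores; default 1000
#'   when `weighted`, 1 otherwise.
#' @return an [interaction_layer].
#' @export
load_interaction_edges <- function(path, weighted = FALSE,
                                   score_scale = if (weighted) 1000 else 1) {
  .assert(is.numeric(score_scale) && score_scale > 0,
          "score_scale must be positive")
  lines <- .read_lines_any(path)
  lines <- lines[nzchar(trimws(lines))]
  .assert(length(lines) > 0, "empty interaction edge file: ", path)
  delim <- .sniff_delim(lines)
  fields <- lapply(lines, .split_fields, delim = delim)
  start <- if (.looks_like_header(fields[[1]], expect_score = weighted)) 2L else 1L
  .assert(length(fields) >= start, "no data rows in interaction file: ", path)
  need <- if (weighted) 3L else 2L
  nf <- vapply(fields, length, 1L)[seq(start, length(fields))]
  bad <- which(nf < need)
  .assert(length(bad) == 0,
          if (weighted && any(nf[bad] == 2))
            "weighted = TRUE but score column missing at line "
          else "malformed interaction row at line ",
          start - 1 + bad[1], " of ", path)
  rows <- fields[seq(start, length(fields))]
  g1 <- vapply(rows, `[`, "", 1)
  g2 <- vapply(rows, `[`, "", 2)
  w <- NULL
  if (weighted) {
    raw <- suppressWarnings(as.numeric(vapply(rows, `[`, "", 3)))
    .assert(!anyNA(raw), "non-numeric score at line ",
            start - 1 + which(is.na(raw))[1], " of ", path)
    .assert(all(raw > 0 & raw <= score_scale),
            "score outside (0, ", score_scale, "] at line ",
            start - 1 + which(!(raw > 0 & raw <= score_scale))[1], " of ", path)
    w <- raw / score_scale
  }
  layer <- interaction_layer(data.frame(gene1 = g1, gene2 = g2), weights = w)
  message("loaded ", nrow(layer$edges),
          if (weighted) " weighted" else " unweighted",
          " interaction edges (", length(layer$genes), " genes) from ", path)
  layer
}

#' Collapse a protein interaction network to a gene network
#'
#' Maps protein identifiers to their encoding genes and, where a gene pair is
#' connected by several protein pairs (genes encoding multiple proteins),
#' keeps the edge of maximum weight. Pairs collapsing onto a single gene
#' become self-loops and are dropped; edges with unmapped proteins are
#' dropped with a reported count.
#'
#' @param protein_edges data frame with columns `protein1`, `protein2` and
#'   optionally `weight` (in (0, 1]; missing means unweighted).
#' @param mapping data frame with columns `protein`, `gene`
#'   (many proteins may map to one gene).
#' @return an [interaction_layer] over gene symbols.
#' @export
map_proteins_to_genes <- function(protein_edges, mapping) {
  protein_edges <- as.data.frame(protein_edges, stringsAsFactors = FALSE)
  mapping <- as.data.frame(mapping, stringsAsFactors = FALSE)
  .assert(nrow(mapping) > 0, "empty protein-to-gene mapping")
  .assert(ncol(mapping) >= 2, "mapping needs columns (protein, gene)")
  .assert(ncol(protein_edges) >= 2, "protein edges need two protein columns")
  prot <- as.character(mapping[[1]])
  gene <- toupper(as.character(mapping[[2]]))
  g1 <- gene[match(as.character(protein_edges[[1]]), prot)]
  g2 <- gene[match(as.character(protein_edges[[2]]), prot)]
  unmapped <- is.na(g1) | is.na(g2)
  if (any(unmapped)) {
    message(sum(unmapped), " protein edge(s) dropped: unmapped protein(s)")
  }
  g1 <- g1[!unmapped]; g2 <- g2[!unmapped]
  w <- if (ncol(protein_edges) >= 3) {
    as.numeric(protein_edges[[3]])[!unmapped]
  } else NULL
  if (length(g1) == 0) {
    return(interaction_layer(data.frame(gene1 = character(0),
                                        gene2 = character(0)),
                             genes = unique(gene)))
  }
  ## interaction_layer() applies the self-loop drop and max-weight collapse
  interaction_layer(data.frame(gene1 = g1, gene2 = g2), weights = w)
}

#' Write layer edge lists as delimited text
#'
#' `write_bipartite_edges()` writes `tumor, gene` rows;
#' `write_interaction_edges()` writes `gene1, gene2[, weight]` rows.
#' Reloading the files reproduces the layers (round-trip safe).
#'
#' @param layer a [bipartite_layer] or [interaction_layer].
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_bipartite_edges <- function(layer, path, sep = "\t") {
  .assert(inherits(layer, "bipartite_layer"), "need a bipartite_layer")
  df <- data.frame(
    tumor = layer$tumors[layer$edges[, 1]],
    gene = layer$genes[layer$edges[, 2]]
  )
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bipartite_edges
#' @export
write_interaction_edges <- function(layer, path, sep = "\t") {
  .assert(inherits(layer, "interaction_layer"), "need an interaction_layer")
  df <- data.frame(
    gene1 = layer$genes[layer$edges[, 1]],
    gene2 = layer$genes[layer$edges[, 2]]
  )
  if (!is.null(layer$weights)) df$weight <- layer$weights
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a two-layer graph to JSON
#'
#' A documented JSON container with node label arrays and edge arrays
#' (plus weights when present), suitable for archiving a run's input graph.
#'
#' @param graph a [two_layer_graph].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_graph_json <- function(graph, path) {
  .assert(inherits(graph, "two_layer_graph"), "need a two_layer_graph")
  obj <- list(
    format = "heatlink-two-layer-graph",
    version = 1L,
    tumors = graph$layer1$tumors,
    genes = graph$layer1$genes,
    has_gene_edges = list(
      tumor = graph$layer1$tumors[graph$layer1$edges[, 1]],
      gene = graph$layer1$genes[graph$layer1$edges[, 2]]
    ),
    interaction_edges = list(
      gene1 = graph$layer2$genes[graph$layer2$edges[, 1]],
      gene2 = graph$layer2$genes[graph$layer2$edges[, 2]],
      weight = graph$layer2$weights
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_graph_json
#' @param path path to a JSON file written by [write_graph_json()].
#' @return `read_graph_json()` returns the reconstructed [two_layer_graph].
#' @export
read_graph_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  .assert(identical(obj$format, "heatlink-two-layer-graph"),
          "not a heatlink graph JSON file: ", path)
  l1 <- bipartite_layer(
    data.frame(tumor = unlist(obj$has_gene_edges$tumor),
               gene = unlist(obj$has_gene_edges$gene)),
    tumors = unlist(obj$tumors), genes = unlist(obj$genes)
  )
  ie <- obj$interaction_edges
  w <- ie$weight
  if (length(w) == 0) w <- NULL
  l2 <- interaction_layer(
    data.frame(gene1 = unlist(ie$gene1), gene2 = unlist(ie$gene2)),
    weights = w, genes = unlist(obj$genes)
  )
  two_layer_graph(l1, l2)
}
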