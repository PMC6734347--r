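test_that("bipartite edge lists load with deduplication and indexing", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("TCGA-B6-A0RG-01\tHOXC4"), f)
  suppressMessages(l <- load_bipartite_edges(f))
  expect_equal(length(l$tumors), 1)
  expect_equal(length(l$genes), 1)
  expect_equal(nrow(l$edges), 1)
  expect_equal(l$genes, "HOXC4")

  writeLines(c("T1,G1", "T1,G1"), f)
  suppressMessages(l <- load_bipartite_edges(f))
  expect_equal(nrow(l$edges), 1)

  ## complete bipartite 3 x 2
  rows <- as.vector(outer(paste0("T", 1:3), paste0("g", 1:2), paste, sep = "\t"))
  writeLines(rows, f)
  suppressMessages(l <- load_bipartite_edges(f))
  expect_equal(nrow(l$edges), 6)
  expect_equal(bipartite_density(l), 1.0)
  expect_true(all(l$genes == toupper(l$genes)))  # symbols uppercased
})

test_that("bipartite loader detects headers and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tumor_id\tgene_symbol", "T1\tG1", "T2\tG2"), f)
  suppressMessages(l <- load_bipartite_edges(f))
  expect_equal(nrow(l$edges), 2)

  writeLines(c("T1\tG1", "JUSTONEFIELD"), f)
  expect_error(suppressMessages(load_bipartite_edges(f)), "line 2")

  writeLines(character(0), f)
  expect_error(load_bipartite_edges(f), "empty")
})

test_that("interaction edge lists scale scores, drop loops, keep max weight", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("G1 G2 700"), f)
  suppressMessages(l <- load_interaction_edges(f, weighted = TRUE))
  expect_equal(l$weights, 0.7)

  writeLines(c("G1 G2 700", "G2 G1 300"), f)
  suppressMessages(l <- load_interaction_edges(f, weighted = TRUE))
  expect_equal(nrow(l$edges), 1)
  expect_equal(l$weights, 0.7)

  writeLines(c("G1 G1 900", "G1 G2 500"), f)
  expect_message(l <- load_interaction_edges(f, weighted = TRUE),
                 "self-loop")
  expect_equal(nrow(l$edges), 1)

  writeLines(c("G1 G2 1500"), f)
  expect_error(suppressMessages(load_interaction_edges(f, weighted = TRUE)),
               "outside")
  writeLines(c("G1 G2"), f)
  expect_error(suppressMessages(load_interaction_edges(f, weighted = TRUE)),
               "line 1")
})

test_that("loaded interaction adjacency is symmetric with zero diagonal", {
  for (seed in 1:3) {
    g <- random_graph(4, 8, weighted = TRUE, seed = seed)
    A <- interaction_adjacency(g$layer2)
    expect_equal(max(abs(A - Matrix::t(A))), 0)
    expect_equal(max(abs(Matrix::diag(A))), 0)
  }
})

test_that("protein networks collapse to gene networks by maximum weight", {
  mapping <- data.frame(protein = c("P1a", "P1b", "P2"),
                        gene = c("g1", "g1", "g2"))
  pe <- data.frame(protein1 = c("P1a", "P1b"), protein2 = c("P2", "P2"),
                   weight = c(0.3, 0.7))
  l <- map_proteins_to_genes(pe, mapping)
  expect_equal(nrow(l$edges), 1)
  expect_equal(l$weights, 0.7)
  expect_setequal(l$genes[l$edges[1, ]], c("G1", "G2"))

  ## pair collapsing to one gene -> self-loop -> dropped
  pe2 <- data.frame(protein1 = "P1a", protein2 = "P1b", weight = 0.5)
  suppressMessages(l2 <- map_proteins_to_genes(pe2, mapping))
  expect_equal(nrow(l2$edges), 0)

  expect_error(map_proteins_to_genes(pe, mapping[0, ]), "empty")
  expect_message(
    map_proteins_to_genes(
      data.frame(protein1 = c("P1a", "PX"), protein2 = c("P2", "P2"),
                 weight = c(0.4, 0.9)), mapping),
    "unmapped")
})

test_that("protein collapse equals the group-by-maximum oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    prots <- sprintf("P%02d", 1:12)
    mapping <- data.frame(protein = prots,
                          gene = sprintf("G%02d", sample(1:6, 12, replace = TRUE)))
    pe <- data.frame(
      protein1 = sample(prots, 10, replace = TRUE),
      protein2 = sample(prots, 10, replace = TRUE),
      weight = round(runif(10, 0.05, 1), 3)
    )
    pe <- pe[pe$protein1 != pe$protein2, ]
    l <- suppressMessages(map_proteins_to_genes(pe, mapping))
    got <- l$weights
    a <- l$genes[l$edges[, 1]]
    b <- l$genes[l$edges[, 2]]
    names(got) <- paste(pmin(a, b), pmax(a, b), sep = "|")
    got <- got[order(names(got))]
    want <- oracle_protein_collapse(pe, mapping)
    expect_equal(names(got), names(want))
    expect_equal(unname(got), as.numeric(want), tolerance = 1e-12)
  }
})

test_that("two-layer assembly takes the union of gene universes", {
  l1 <- bipartite_layer(data.frame(tumor = "T1", gene = c("A", "B")))
  l2 <- interaction_layer(data.frame(gene1 = "B", gene2 = "C"))
  g <- two_layer_graph(l1, l2)
  expect_setequal(g$layer1$genes, c("A", "B", "C"))
  expect_identical(g$layer1$genes, g$layer2$genes)
  ## A is isolated in layer 2
  A <- interaction_adjacency(g$layer2)
  expect_equal(sum(A[match("A", g$layer2$genes), ]), 0)

  ## disjoint gene sets: interaction component unreachable from seeds
  g2 <- two_layer_graph(
    bipartite_layer(data.frame(tumor = "T1", gene = "A")),
    interaction_layer(data.frame(gene1 = "X", gene2 = "Y"))
  )
  expect_equal(length(g2$layer1$genes), 3)
  f1 <- diffuse_exact(build_heat_matrix_weighted(g2$layer2),
                      seed_vector(g2, "T1"), alpha = 1)
  expect_equal(unname(f1[match(c("X", "Y"), g2$layer1$genes)]), c(0, 0))
})

test_that("graphs round-trip through edge-list and JSON serialization", {
  g <- random_graph(5, 9, weighted = TRUE, seed = 11)
  d <- withr::local_tempdir()
  write_bipartite_edges(g$layer1, file.path(d, "l1.tsv"))
  write_interaction_edges(g$layer2, file.path(d, "l2.tsv"))
  suppressMessages({
    l1 <- load_bipartite_edges(file.path(d, "l1.tsv"))
    l2 <- load_interaction_edges(file.path(d, "l2.tsv"), weighted = TRUE,
                                 score_scale = 1)
  })
  g2 <- two_layer_graph(l1, l2)
  key <- function(l, e) paste(l$tumors[e[, 1]], l$genes[e[, 2]])
  expect_setequal(key(g2$layer1, g2$layer1$edges), key(g$layer1, g$layer1$edges))
  ikey <- function(l) paste(l$genes[l$edges[, 1]], l$genes[l$edges[, 2]],
                            signif(l$weights, 10))
  expect_setequal(ikey(g2$layer2), ikey(g$layer2))

  write_graph_json(g, file.path(d, "g.json"))
  g3 <- read_graph_json(file.path(d, "g.json"))
  expect_setequal(ikey(g3$layer2), ikey(g$layer2))
  expect_identical(graph_summary(g3), graph_summary(g))
})

test_that("summary counts describe the graph", {
  g <- toy_fixture()
  s <- graph_summary(g)
  expect_equal(s$n_tumors, 1)
  expect_equal(s$n_genes, 4)
  expect_equal(s$n_has_gene, 3)
  expect_equal(s$n_interactions, 2)
  expect_equal(s$bipartite_density, 0.75)
})
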