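test_that("unweighted heat matrix follows the degree-Laplacian form", {
  ## single edge on 2 nodes
  l2 <- interaction_layer(data.frame(gene1 = "A", gene2 = "B"))
  H <- build_heat_matrix_unweighted(l2)
  expect_equal(as.matrix(H$mat), matrix(c(-1, 1, 1, -1), 2),
               ignore_attr = TRUE)

  ## triangle
  l2 <- interaction_layer(data.frame(gene1 = c("A", "B", "C"),
                                     gene2 = c("B", "C", "A")))
  M <- as.matrix(build_heat_matrix_unweighted(l2)$mat)
  expect_equal(unname(diag(M)), rep(-2, 3))
  expect_equal(unname(M[upper.tri(M)]), rep(1, 3))

  ## edgeless graph
  l2 <- interaction_layer(data.frame(gene1 = character(0),
                                     gene2 = character(0)),
                          genes = c("A", "B"))
  expect_equal(max(abs(build_heat_matrix_unweighted(l2)$mat)), 0)
})

test_that("degree-normalized heat matrix handles weights and isolates", {
  l2 <- interaction_layer(data.frame(gene1 = "A", gene2 = "B"),
                          weights = 0.5)
  H <- build_heat_matrix_weighted(l2)
  expect_equal(as.matrix(H$mat), matrix(c(-0.5, 0.5, 0.5, -0.5), 2),
               ignore_attr = TRUE)

  ## isolated node: zero row and column (tau = 0 keeps its heat)
  l2 <- interaction_layer(data.frame(gene1 = "A", gene2 = "B"),
                          weights = 0.5, genes = c("A", "B", "C"))
  M <- as.matrix(build_heat_matrix_weighted(l2)$mat)
  expect_equal(unname(M[3, ]), rep(0, 3))
  expect_equal(unname(M[, 3]), rep(0, 3))

  ## random weighted graphs: columns sum to zero
  for (seed in 1:4) {
    g <- random_graph(2, 6, weighted = TRUE, seed = seed)
    H <- build_heat_matrix_weighted(g$layer2)
    expect_lt(max(abs(Matrix::colSums(H$mat))), 1e-12)
    Hu <- build_heat_matrix_unweighted(g$layer2)
    expect_lt(max(abs(Matrix::colSums(Hu$mat))), 1e-12)
  }
})

test_that("teleport augmentation is the rank-1 uniform-jump correction", {
  l2 <- interaction_layer(data.frame(gene1 = "A", gene2 = "B"),
                          genes = c("A", "B", "C", "D"))
  H <- build_heat_matrix_unweighted(l2)
  f0 <- c(1, 0, 2, 0)

  ## gamma = 1: identical operator
  R1 <- add_teleport(H, 1)
  expect_equal(diffuse_exact(R1, f0, 1), diffuse_exact(H, f0, 1))

  ## gamma = 0, n = 4: every column of the dense operator is 1/4
  R0 <- add_teleport(H, 0)
  D <- heatlink:::.heat_dense(R0)
  expect_equal(unname(D), matrix(0.25, 4, 4))

  ## gamma = 0.85: entrywise 0.85 H + 0.0375
  R <- add_teleport(H, 0.85)
  expect_equal(unname(heatlink:::.heat_dense(R)),
               unname(0.85 * as.matrix(H$mat) + 0.15 / 4))

  ## the implicit product matches the dense operator
  expect_equal(as.numeric(heatlink:::.heat_apply(R, f0)),
               as.numeric(heatlink:::.heat_dense(R) %*% f0))

  expect_error(add_teleport(H, 1.2), "gamma")
})

test_that("seed vectors are binary indicators of training links", {
  g <- toy_fixture()
  expect_equal(unname(seed_vector(g, "TumorX")), c(1, 1, 1, 0))
  expect_error(seed_vector(g, "NoSuchTumor"), "unknown tumor")

  none <- g$layer1$edges[0, , drop = FALSE]
  expect_equal(unname(seed_vector(g, "TumorX", none)), rep(0, 4))

  all_edges <- cbind(tumor = 1L, gene = 1:4)
  expect_equal(unname(seed_vector(g, "TumorX", all_edges)), rep(1, 4))
})

test_that("exact diffusion reproduces hand-computable cases", {
  g <- toy_fixture()
  H <- build_heat_matrix_unweighted(g$layer2)
  f0 <- seed_vector(g, "TumorX")

  ## alpha = 0: no diffusion at all
  expect_equal(diffuse_exact(H, f0, 0), f0)

  ## the literal printed toy operator sends (1 - e^-2)/2 to the unseeded gene
  Hp <- as_heat_matrix(toy_printed_heat_matrix())
  f1 <- diffuse_exact(Hp, c(1, 1, 1, 0), 1)
  expect_equal(unname(f1[4]), (1 - exp(-2)) / 2, tolerance = 1e-12)
  expect_equal(round(unname(f1[4]), 2), 0.43)

  ## symmetric 2-node edge equilibrates to the mean for large alpha
  l2 <- interaction_layer(data.frame(gene1 = "A", gene2 = "B"))
  H2 <- build_heat_matrix_unweighted(l2)
  expect_equal(unname(diffuse_exact(H2, c(1, 0), 50)), c(0.5, 0.5),
               tolerance = 1e-9)

  expect_error(diffuse_exact(H, f0, 1, max_n = 2), "diffuse_discrete")
})

test_that("discrete diffusion is a single resolvent step at M = 1", {
  l2 <- interaction_layer(data.frame(gene1 = c("A", "B"),
                                     gene2 = c("B", "C")))
  H <- build_heat_matrix_weighted(l2)
  f0 <- c(1, 0, 0)
  got <- diffuse_discrete(H, f0, diffusion_params(alpha = 1, M = 1,
                                                  teleport = FALSE))
  want <- f0 + as.numeric(H$mat %*% f0)
  expect_equal(unname(got), want)
})

test_that("discrete diffusion converges monotonically to the exponential", {
  for (seed in 1:3) {
    g <- random_graph(3, 20, p_int = 0.2, weighted = TRUE, seed = seed)
    H <- add_teleport(build_heat_matrix_weighted(g$layer2), 0.85)
    f0 <- as.numeric(seq_len(20) %% 3 == 0)
    exact <- diffuse_exact(H, f0, 1)
    errs <- vapply(c(1, 10, 100, 1000), function(M) {
      max(abs(diffuse_discrete(H, f0, diffusion_params(M = M)) - exact))
    }, 0)
    expect_lt(errs[4], 1e-3)
    expect_true(all(diff(errs) < 0))
  }
})

test_that("heat is conserved without teleport and grows as e^(alpha(1-gamma)) with it", {
  for (seed in 1:3) {
    g <- random_graph(3, 12, weighted = seed != 2, seed = seed)
    f0 <- runif(12)
    for (build in list(build_heat_matrix_unweighted, build_heat_matrix_weighted)) {
      H <- build(g$layer2)
      expect_equal(sum(diffuse_exact(H, f0, 1.3)), sum(f0), tolerance = 1e-9)
      R <- add_teleport(H, 0.85)
      expect_equal(sum(diffuse_exact(R, f0, 1.3)),
                   exp(1.3 * 0.15) * sum(f0), tolerance = 1e-9)
      got <- diffuse_discrete(R, f0, diffusion_params(alpha = 1.3, M = 7))
      expect_equal(sum(got), (1 + 1.3 * 0.15 / 7)^7 * sum(f0),
                   tolerance = 1e-9)
    }
  }
})

test_that("normalization maps the printed toy vector to the printed shares", {
  f <- normalize_heat(c(1.0, 1.0, 0.5, 0.43))
  expect_equal(round(f, 2), c(0.34, 0.34, 0.17, 0.15))
  expect_equal(f[1:3], c(0.34, 0.34, 0.17), tolerance = 0.005)

  expect_equal(normalize_heat(5), 1)
  for (seed in 1:3) {
    set.seed(seed)
    v <- runif(10, 0.01, 5)
    expect_equal(sum(normalize_heat(v)), 1, tolerance = 1e-12)
  }
  expect_warning(z <- normalize_heat(c(0, 0)), "zero")
  expect_equal(z, c(0, 0))
})

test_that("normalization never reorders a tumor's scores", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- runif(30)
    expect_equal(order(normalize_heat(v)), order(v))
  }
})

test_that("candidate scoring ranks the toy target gene with positive heat", {
  g <- toy_fixture()
  st <- score_tumors(g)
  expect_s3_class(st, "score_table")
  expect_equal(st$gene, "D")      # only candidate
  expect_gt(st$score, 0)
  expect_equal(st$rank, 1)

  ## alpha = 0 without teleport: all candidates tied at zero
  g2 <- random_graph(4, 6, seed = 5)
  st2 <- score_tumors(g2, params = diffusion_params(alpha = 0, teleport = FALSE,
                                                    normalize_output = FALSE))
  expect_true(all(st2$score == 0))
  expect_true(all(st2$rank == 1))

  expect_equal(nrow(score_tumors(g, tumors = character(0))), 0)
})

test_that("held-out planted genes outscore random non-edges on average", {
  sim <- generate_two_layer(n_tumors = 60, n_genes = 80,
                            bipartite_density = 0.05, seed = 9,
                            holdout_fraction = 0.3)
  g <- sim$graph
  held_idx <- cbind(match(sim$held_out$tumor, g$layer1$tumors),
                    match(sim$held_out$gene, g$layer1$genes))
  keys_all <- (g$layer1$edges[, 1] - 1) * 80 + g$layer1$edges[, 2]
  keys_held <- (held_idx[, 1] - 1) * 80 + held_idx[, 2]
  train <- g$layer1$edges[!(keys_all %in% keys_held), , drop = FALSE]
  st <- suppressWarnings(score_tumors(g, train_edges = train))
  key_st <- (match(st$tumor, g$layer1$tumors) - 1) * 80 +
    match(st$gene, g$layer1$genes)
  pos <- st$score[key_st %in% keys_held]
  neg <- st$score[!(key_st %in% keys_held)]
  expect_gt(mean(pos), mean(neg))
  expect_gt(auc_roc(pos, neg), 0.7)
})

test_that("non-negative seeds give non-negative scores when M >= alpha", {
  for (seed in 1:3) {
    g <- random_graph(3, 15, weighted = TRUE, seed = seed)
    H <- add_teleport(build_heat_matrix_weighted(g$layer2), 0.85)
    set.seed(seed)
    f0 <- runif(15)
    out <- diffuse_discrete(H, f0, diffusion_params(alpha = 2, M = 4))
    expect_true(all(out >= 0))
  }
})

test_that("degree normalization curbs hub-score inflation on a star graph", {
  set.seed(42)
  n <- 60
  genes <- sprintf("G%03d", 1:n)
  extra <- t(combn(2:n, 2))
  extra <- extra[sample(nrow(extra), 150), ]
  l2 <- interaction_layer(rbind(
    data.frame(gene1 = "G001", gene2 = genes[2:n]),
    data.frame(gene1 = genes[extra[, 1]], gene2 = genes[extra[, 2]])
  ))
  pairs <- do.call(rbind, lapply(1:20, function(t) {
    data.frame(tumor = sprintf("T%02d", t),
               gene = genes[sample(2:n, 5)])
  }))
  g <- two_layer_graph(bipartite_layer(pairs, genes = genes), l2)
  hub_share <- function(dn) {
    st <- score_tumors(g, params = diffusion_params(normalize_output = FALSE),
                       degree_normalized = dn)
    mean(vapply(split(st, st$tumor), function(d) {
      abs(d$score[d$gene == "G001"]) / sum(abs(d$score))
    }, 0))
  }
  expect_lt(hub_share(TRUE), hub_share(FALSE))
})
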