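test_that("shortest-path matrix equals a Floyd-Warshall oracle on random graphs", {
  for (s in 1:30) {
    n <- sample(4:12, 1)
    net <- random_connected_net(n, extra = sample(0:6, 1), seed = s)
    expect_equal(all_pairs_shortest_path(net), fw_distances(net$n, net$edges))
  }
})

test_that("shortest paths: zero diagonal and two-hop paths", {
  net <- ppi_network(cbind(c("A", "B"), c("B", "C")))
  d <- all_pairs_shortest_path(net)
  expect_equal(diag(d), c(0, 0, 0))
  expect_equal(d[1, 3], 2)
  disc <- ppi_network(cbind(c("A", "C"), c("B", "D")))
  expect_error(all_pairs_shortest_path(disc), "disconnected")
})

test_that("MST context carries degrees and tree distances", {
  tree <- varied_tree()
  ctx <- mst_context(tree)
  expect_equal(sum(ctx$deg), 2L * (tree$n - 1L))
  expect_equal(ctx$max_deg, 4L)  # hub H has degree 4
  expect_true(all(ctx$sp == t(ctx$sp)))
  expect_error(mst_context(random_connected_net(8, extra = 4, seed = 1)),
               "spanning tree")
})

test_that("edge probabilities reproduce the three model definitions", {
  # duplication band: alpha regardless of degrees
  expect_equal(edge_probability(2, 1, 1, 4, "daneosf", alpha = 0.3), 0.3)
  expect_equal(edge_probability(3, 4, 2, 4, "daneosf", alpha = 0.3), 0.3)
  # neofunctionalization with maximal degrees: base ratio 1 -> probability 1
  expect_equal(edge_probability(5, 4, 4, 4, "daneosf"), 1)
  # independent arithmetic for the general neofunctionalization branch
  expect_equal(edge_probability(4, 2, 3, 4, "daneosf"), (6 / 16)^4)
  # random mutation: beta for any non-adjacent pair
  expect_equal(edge_probability(7, 1, 3, 5, "rm", beta = 0.15), 0.15)
  # preferential attachment at maximal degrees: 1/2
  expect_equal(edge_probability(9, 4, 4, 4, "lpa"), 0.5)
  # adjacency always collapses to 1
  expect_equal(edge_probability(1, 1, 1, 9, "daneosf"), 1)
  expect_equal(edge_probability(1, 1, 1, 9, "lpa"), 1)
  expect_equal(edge_probability(1, 1, 1, 9, "rm"), 1)
})

test_that("edge probabilities stay in [0, 1] across all degree/distance combos", {
  for (model in c("daneosf", "lpa", "rm")) {
    for (dmax in c(2, 5, 11)) {
      grid <- expand.grid(sp = 1:12, di = 1:dmax, dj = 1:dmax)
      p <- edge_probability(grid$sp, grid$di, grid$dj, dmax, model)
      expect_true(all(p >= 0 & p <= 1))
    }
  }
})

test_that("toy fixture intermediates match the implementation", {
  tf <- toy_fixture()
  expect_equal(tf$component$n, 5L)
  expect_equal(nrow(tf$mst), 4L)
  ctx <- mst_context(subnetwork(tf$component, tf$mst))
  expect_equal(ctx$sp, tf$sp)
  p <- edge_probability_matrix(ctx, "daneosf")
  expect_equal(p[upper.tri(p)], tf$daneosf_probs[upper.tri(p)])
})

test_that("random mutation extremes: beta 0 keeps the MST, beta 1 completes the graph", {
  tree <- varied_tree()
  ctx <- mst_context(tree)
  ev0 <- sample_evolved_network(tree, ctx, evo_params("rm", beta = 0,
                                                     seed = 1))
  expect_identical(ev0$edges, tree$edges)
  ev1 <- sample_evolved_network(tree, ctx, evo_params("rm", beta = 1,
                                                     seed = 1))
  expect_equal(ev1$m_edges, choose(tree$n, 2))
})

test_that("sampled acceptance rates agree with model probabilities (3 sigma)", {
  tree <- varied_tree()
  ctx <- mst_context(tree)
  p <- edge_probability_matrix(ctx, "daneosf")
  band <- upper.tri(ctx$sp) & ctx$sp >= 2 & ctx$sp <= 3
  runs <- 300L
  hits <- 0L
  for (r in seq_len(runs)) {
    ev <- sample_evolved_network(tree, ctx,
                                 evo_params("daneosf", seed = 1000 + r))
    a <- matrix(FALSE, tree$n, tree$n)
    a[ev$edges] <- TRUE
    hits <- hits + sum(a[band])
  }
  expected <- runs * sum(p[band])
  se <- sqrt(runs * sum(p[band] * (1 - p[band])))
  expect_lt(abs(hits - expected), 3 * se)
})

test_that("evolved edges carry origin flags by model band", {
  tree <- varied_tree()
  ctx <- mst_context(tree)
  ev <- sample_evolved_network(tree, ctx, evo_params("daneosf", seed = 4))
  expect_equal(sum(ev$edge_origin == "mst"), tree$m_edges)
  added <- ev$edges[ev$edge_origin != "mst", , drop = FALSE]
  for (r in seq_len(nrow(added))) {
    sp <- ctx$sp[added[r, 1], added[r, 2]]
    expect_equal(ev$edge_origin[ev$edge_origin != "mst"][r],
                 if (sp <= 3) "duplication" else "neofunctionalization")
  }
  evr <- sample_evolved_network(tree, ctx, evo_params("rm", seed = 4))
  expect_true(all(evr$edge_origin %in% c("mst", "mutation")))
})

test_that("literal mode with beta 0 reproduces the MST distance matrix", {
  tree <- varied_tree()
  ctx <- mst_context(tree)
  ed <- evolutionary_distance_matrix(
    tree, ctx, evo_params("rm", beta = 0, mode = "literal", seed = 2))
  expect_identical(ed$dist, ctx$sp)
})

test_that("evolved-graph distances never exceed MST distances and match a brute-force oracle", {
  net <- random_connected_net(10, extra = 6, seed = 8)
  mst <- minimum_spanning_tree(net, seed = 3)
  mst_net <- subnetwork(net, mst)
  ctx <- mst_context(mst_net)
  ed <- evolutionary_distance_matrix(mst_net, ctx,
                                     evo_params("daneosf", seed = 21))
  expect_true(all(ed$dist <= ctx$sp))
  # oracle: materialize the sampled edge list, run Floyd-Warshall
  expect_equal(ed$dist, fw_distances(net$n, ed$evolved$edges))
})

test_that("a fixed seed reproduces the evolved network and matrix bit for bit", {
  tree <- varied_tree()
  ctx <- mst_context(tree)
  p <- evo_params("daneosf", seed = 77)
  e1 <- evolutionary_distance_matrix(tree, ctx, p)
  e2 <- evolutionary_distance_matrix(tree, ctx, p)
  expect_identical(e1, e2)
})
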