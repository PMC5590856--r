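test_that("edge-list parsing drops self-loops, collapses duplicates, skips comments", {
  f <- withr::local_tempfile(lines = c("# interactions", "A\tB", "B C",
                                       "B\tA", "C C"))
  net <- suppressMessages(parse_edge_list(f, dialect = "tsv"))
  expect_equal(net$node_ids, c("A", "B", "C"))
  expect_equal(net$edges, cbind(i = c(1L, 2L), j = c(2L, 3L)))
  st <- attr(net, "parse_stats")
  expect_equal(st$self_loops_dropped, 1L)
  expect_equal(st$duplicates_collapsed, 1L)
  expect_equal(st$lines_read, 4L)

  f2 <- withr::local_tempfile(lines = c("# c", "A B", "A C"))
  net2 <- suppressMessages(parse_edge_list(f2))
  expect_equal(net2$n, 3L)
  expect_equal(net2$m_edges, 2L)
})

test_that("mitab dialect reads interactor identifiers from columns 1 and 2", {
  f <- withr::local_tempfile(lines = c(
    "#ID(A)\tID(B)\talias\tmethod",
    "uniprot:P1\tuniprot:P2\tx\ty",
    "uniprot:P2\tuniprot:P3\tx\ty"))
  net <- suppressMessages(parse_edge_list(f, dialect = "mitab"))
  expect_equal(net$node_ids, c("uniprot:P1", "uniprot:P2", "uniprot:P3"))
  expect_equal(net$m_edges, 2L)
})

test_that("parsing errors name the problem", {
  expect_error(parse_edge_list(file.path(tempdir(), "nope.tsv")),
               "cannot read")
  f <- withr::local_tempfile(lines = c("A B", "lonely"))
  expect_error(suppressMessages(parse_edge_list(f)), "line 2")
  f2 <- withr::local_tempfile(lines = "# only a comment")
  expect_error(suppressMessages(parse_edge_list(f2)), "no interaction")
})

test_that("write-then-parse round-trip preserves a 1,000-edge network exactly", {
  net <- random_geometric_network(220, geo_dim = 2, radius = 0.13,
                                  seed = 42)
  expect_gt(net$m_edges, 1000)
  f <- withr::local_tempfile()
  write_edge_list(net, f)
  back <- suppressMessages(parse_edge_list(f))
  # isolated nodes cannot appear in an edge list; the edge set itself
  # (as identifier pairs) must survive the round trip exactly
  id_pairs <- function(x) paste(x$node_ids[x$edges[, 1]],
                                x$node_ids[x$edges[, 2]])
  expect_identical(id_pairs(back), id_pairs(net))
  expect_equal(back$m_edges, net$m_edges)
})

test_that("maximum connected component extraction and tie-breaking", {
  # disjoint triangle plus a single edge: the triangle wins
  net <- ppi_network(cbind(c("A", "B", "C", "D"), c("B", "C", "A", "E")))
  comp <- max_connected_component(net)
  expect_equal(comp$node_ids, c("A", "B", "C"))
  expect_equal(comp$m_edges, 3L)
  # connected network is returned unchanged
  expect_identical(max_connected_component(comp)[], comp[])
  # size tie broken toward the lexicographically smallest node id
  tied <- ppi_network(cbind(c("B", "A"), c("C", "D")))
  expect_equal(max_connected_component(tied)$node_ids, c("A", "D"))
})

test_that("MST draws are spanning trees for every seed and vary across seeds", {
  square <- ppi_network(cbind(c("A", "B", "C", "D"),
                              c("B", "C", "D", "A")))
  seen <- character(0)
  for (s in 1:50) {
    mst <- minimum_spanning_tree(square, seed = s)
    expect_equal(nrow(mst), 3L)
    expect_true(is_forest(4L, mst))
    expect_setequal(unique(as.vector(mst)), 1:4)
    seen <- c(seen, paste(t(mst), collapse = ","))
  }
  expect_gte(length(unique(seen)), 2L)
  # tree-shaped input: the MST is the input edge set for any seed
  tree <- random_connected_net(12, extra = 0, seed = 3)
  expect_identical(minimum_spanning_tree(tree, seed = 9), tree$edges)
  # same seed is fully reproducible
  net <- random_connected_net(30, extra = 40, seed = 5)
  expect_identical(minimum_spanning_tree(net, seed = 7),
                   minimum_spanning_tree(net, seed = 7))
})

test_that("MST invariants hold on random connected graphs (union-find oracle)", {
  for (s in 1:10) {
    net <- random_connected_net(25, extra = 30, seed = s)
    mst <- minimum_spanning_tree(net, seed = s + 100)
    expect_equal(nrow(mst), net$n - 1L)
    expect_true(is_forest(net$n, mst))
    expect_true(all(paste(mst[, 1], mst[, 2]) %in%
                      paste(net$edges[, 1], net$edges[, 2])))
  }
})

test_that("MST refuses disconnected input", {
  net <- ppi_network(cbind(c("A", "C"), c("B", "D")))
  expect_error(minimum_spanning_tree(net), "disconnected")
})

test_that("train/test split accounting matches the candidate-pair identity", {
  net <- random_connected_net(40, extra = 60, seed = 2)
  mst <- minimum_spanning_tree(net, seed = 11)
  sp <- split_train_test(net, mst)
  expect_equal(nrow(sp$trn_edges), net$n - 1L)
  expect_equal(nrow(sp$trn_edges) + nrow(sp$tst_edges), net$m_edges)
  expect_equal(sp$n_candidates, choose(net$n, 2) - (net$n - 1))
  expect_equal(nrow(merge(as.data.frame(sp$trn_edges),
                          as.data.frame(sp$tst_edges))), 0L)
  # a pure tree leaves no test edges
  tree <- random_connected_net(15, extra = 0, seed = 4)
  sp2 <- split_train_test(tree, tree$edges)
  expect_equal(nrow(sp2$tst_edges), 0L)
  # foreign MST edges are rejected
  bad <- rbind(mst[-1, ], c(1L, net$n))
  expect_error(split_train_test(net, bad), "absent|spanning")
})

test_that("adjacency matrix is symmetric 0/1 with zero diagonal", {
  net <- random_connected_net(10, extra = 8, seed = 6)
  a <- adjacency_matrix(net)
  expect_true(all(diag(a) == 0))
  expect_identical(a, t(a))
  expect_equal(sum(a), 2L * net$m_edges)
})
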