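test_that("read_edge_list parses, collapses duplicates, rejects self-loops", {
  g <- read_edge_list(c("1 2", "2 3"))
  expect_identical(g$vertices, c("1", "2", "3"))
  expect_identical(edge_matrix(g),
                   cbind(source = c("1", "2"), target = c("2", "3")))

  expect_warning(g2 <- read_edge_list(c("a b", "a b")), "duplicate")
  expect_identical(ecount(g2), 1L)

  expect_error(read_edge_list("x x"), "self-loop at line 1")
  expect_error(read_edge_list(c("a b", "justone")), "line 2")

  # comments, blanks, extra annotation tokens
  expect_message(
    g3 <- read_edge_list(c("# header", "", "a b 1.5", "b c")),
    "extra tokens")
  expect_identical(ecount(g3), 2L)
})

test_that("edge-list writer round-trips vertex and edge sets", {
  for (seed in 1:20) {
    g <- random_connected_digraph(sample(4:10, 1), sample(6:14, 1), seed)
    g2 <- read_edge_list(write_edge_list(g))
    expect_setequal(g2$vertices, g$vertices)
    expect_true(graph_identical(g, g2))
  }
  tmp <- withr::local_tempfile()
  g <- fig4_graph()
  write_edge_list(g, tmp)
  expect_true(graph_identical(read_edge_list(tmp), g))
})

test_that("incidence matrix matches the printed 4-cycle normalization", {
  g <- digraph(rbind(c("1", "3"), c("3", "2"), c("2", "4"), c("4", "1")))
  m <- incidence_matrix(g, vertex_order = c("1", "3", "2", "4"))
  expect_identical(unname(m),
                   rbind(c(1L, 0L, 0L, -1L), c(-1L, 1L, 0L, 0L),
                         c(0L, -1L, 1L, 0L), c(0L, 0L, -1L, 1L)))
})

test_that("incidence matrix invariants hold on random graphs", {
  g1 <- digraph(rbind(c("u", "v")))
  expect_identical(unname(incidence_matrix(g1)), rbind(1L, -1L))
  for (seed in 1:10) {
    g <- random_digraph(7, sample(5:20, 1), seed)
    m <- incidence_matrix(g)
    expect_true(all(colSums(m) == 0L))
    expect_identical(sum(m == 1L), ecount(g))
    expect_identical(sum(m == -1L), ecount(g))
    expect_identical(sum(m), 0L)
  }
  expect_error(incidence_matrix(g1, vertex_order = c("u", "u")),
               "permutation")
  expect_error(incidence_matrix(g1, edge_order = c(2L)), "permutation")
})

test_that("induced subgraph uses induced semantics", {
  g <- cycle_graph(c("1", "2", "3", "4"))
  # brute force over the four 3-subsets: each induces a 2-edge path
  for (drop in g$vertices) {
    sub <- induced_subgraph(g, setdiff(g$vertices, drop))
    expect_identical(ecount(sub), 2L)
    expect_true(is_weakly_connected(sub))
  }
  expect_true(graph_identical(induced_subgraph(g, g$vertices), g))
  lone <- induced_subgraph(g, "2")
  expect_identical(vcount(lone), 1L)
  expect_identical(ecount(lone), 0L)
  expect_error(induced_subgraph(g, "zz"), "unknown vertex")
})

test_that("degree pairs are exact and sum to the edge count", {
  g3 <- cycle_graph(c("1", "2", "3"))
  expect_identical(degree_pair(g3, "2"), c(d_in = 1L, d_out = 1L))
  expect_identical(degree_pair(star_graph(), "h"), c(d_in = 0L, d_out = 3L))
  # worked parity-node example: node 2 has in-degree 1, out-degree 2
  expect_identical(degree_pair(fig4_graph(), "2"), c(d_in = 1L, d_out = 2L))
  for (seed in 1:10) {
    g <- random_digraph(8, sample(0:30, 1), seed)
    dp <- degree_pairs(g)
    expect_identical(sum(dp[, "d_in"]), ecount(g))
    expect_identical(sum(dp[, "d_out"]), ecount(g))
  }
  expect_error(degree_pair(g3, "nope"), "unknown vertex")
})

test_that("weak connectivity ignores direction", {
  expect_true(is_weakly_connected(cycle_graph(c("1", "2", "3"))))
  expect_false(is_weakly_connected(
    digraph(rbind(c("a", "b"), c("c", "d")))))
  expect_true(is_weakly_connected(
    digraph(rbind(c("1", "2"), c("3", "2")))))
  expect_true(is_weakly_connected(digraph(vertices = "solo")))
  expect_error(is_weakly_connected(digraph()), "empty")
})

test_that("digraph constructor rejects self-loops and validates input", {
  expect_error(digraph(rbind(c("x", "x"))), "self-loop")
  expect_warning(digraph(rbind(c("a", "b"), c("a", "b"))), "duplicate")
  expect_identical(vcount(digraph()), 0L)
})
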