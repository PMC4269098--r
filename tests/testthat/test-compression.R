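test_that("structural parity classes on the worked 5-node example", {
  g <- fig4_graph()
  classes <- find_parity_classes(g)
  keys <- vapply(classes, function(cl) paste(cl$members, collapse = ","),
                 character(1))
  expect_setequal(keys, c("2,4", "1,3", "5"))
  c24 <- classes[[which(keys == "2,4")]]
  expect_identical(c24$representative, "2")
  expect_identical(c24$degree, c(d_in = 1L, d_out = 2L))
  expect_identical(c24$twin_kind, "false_twin")
  c13 <- classes[[which(keys == "1,3")]]
  expect_identical(c13$twin_kind, "false_twin")
  expect_identical(c13$degree, c(d_in = 2L, d_out = 0L))
})

test_that("degree vs structural mode on the directed 3-cycle", {
  g <- cycle_graph(c("1", "2", "3"))
  dg <- find_parity_classes(g, "degree")
  expect_identical(length(dg), 1L)
  expect_setequal(dg[[1]]$members, c("1", "2", "3"))
  st <- find_parity_classes(g, "structural")
  expect_identical(length(st), 3L)
  expect_true(all(lengths(lapply(st, `[[`, "members")) == 1L))
})

test_that("true twins (mutually connected pairs) are detected", {
  g <- digraph(rbind(c("a", "b"), c("b", "a"), c("a", "x"), c("b", "x"),
                     c("y", "a"), c("y", "b")))
  classes <- find_parity_classes(g)
  keys <- vapply(classes, function(cl) paste(cl$members, collapse = ","),
                 character(1))
  expect_true("a,b" %in% keys)
  expect_identical(classes[[which(keys == "a,b")]]$twin_kind, "true_twin")
})

test_that("compress produces the stated G_r / G_p / G_cv partition", {
  g <- fig4_graph()
  cg <- compress(g)
  expect_setequal(cg$g_r$vertices, c("1", "2", "5"))
  expect_setequal(paste(edge_matrix(cg$g_r)[, 1], edge_matrix(cg$g_r)[, 2]),
                  c("2 1", "5 2"))
  expect_setequal(cg$g_p, c("3", "4"))
  expect_setequal(paste(cg$g_cv[, 1], cg$g_cv[, 2]),
                  c("2 3", "4 1", "4 3", "5 4"))
  # partition invariants
  expect_setequal(c(cg$g_r$vertices, cg$g_p), g$vertices)
  expect_identical(ecount(cg$g_r) + nrow(cg$g_cv), ecount(g))
  expect_identical(cg$multiplicity[["2"]], 2L)

  star <- star_graph()
  cs <- compress(star)
  expect_identical(ecount(cs$g_r), 1L)
  expect_identical(cs$multiplicity[["a"]], 3L)

  g3 <- cycle_graph(c("1", "2", "3"))
  ci <- compress(g3)
  expect_true(graph_identical(ci$g_r, g3))
  expect_identical(length(ci$g_p), 0L)
  expect_identical(nrow(ci$g_cv), 0L)
})

test_that("compression never grows, equality iff no class of size >= 2", {
  for (seed in 1:15) {
    pg <- planted_twin_graph(seed)
    cg <- compress(pg$graph)
    expect_lte(vcount(cg$g_r), vcount(pg$graph))
    expect_lte(ecount(cg$g_r), ecount(pg$graph))
    nontrivial <- any(cg$multiplicity >= 2L)
    expect_identical(vcount(cg$g_r) < vcount(pg$graph), nontrivial)
  }
})

test_that("exchanging structural parity nodes is a graph automorphism", {
  g <- fig4_graph()
  expect_true(graph_identical(swap_labels(g, "2", "4"), g))
  expect_true(graph_identical(swap_labels(g, "1", "3"), g))
  for (seed in 1:20) {
    pg <- planted_twin_graph(seed + 100L)
    classes <- find_parity_classes(pg$graph)
    for (cl in classes) {
      if (length(cl$members) < 2L) next
      swapped <- swap_labels(pg$graph, cl$members[1], cl$members[2])
      expect_true(graph_identical(swapped, pg$graph))
    }
  }
})

test_that("expand-mode compressed census equals the direct census", {
  star <- star_graph()
  cen2 <- census_compressed(compress(star), 2, expand = TRUE)
  expect_identical(unname(cen2$counts[1]), 3)
  cen3 <- census_compressed(compress(star), 3, expand = TRUE)
  expect_identical(unname(cen3$counts[1]), 3)
  expect_census_equal(cen3, subgraph_census(star, 3))

  # paper-faithful fast mode censuses only the retained graph
  fast <- census_compressed(compress(star), 2, expand = FALSE)
  expect_identical(unname(fast$counts[1]), 1)

  # identity compression: both modes equal the direct census
  g3 <- cycle_graph(c("1", "2", "3"))
  expect_census_equal(census_compressed(compress(g3), 3, expand = TRUE),
                      subgraph_census(g3, 3))
  expect_census_equal(census_compressed(compress(g3), 3, expand = FALSE),
                      subgraph_census(g3, 3))
})

test_that("compressed_census reports distinct multiset embeddings", {
  star <- star_graph()
  cc <- compressed_census(compress(star), 2)
  expect_identical(length(cc$entries), 1L)
  expect_identical(cc$entries[[1]]$n_embeddings, 1)
  expect_identical(cc$entries[[1]]$usage, c(a = 1L))
  ex <- expand_census(cc, 2)
  expect_identical(unname(ex$counts[1]), 3)
  expect_error(expand_census(cc, 3), "does not match")
})

test_that("degree-mode classes trigger the count-unsafe warning", {
  g <- cycle_graph(c("1", "2", "3", "4"))
  cg <- compress(g, find_parity_classes(g, "degree"))
  expect_warning(compressed_census(cg, 3), "not exact")
})

test_that("compress validates its class argument", {
  g <- fig4_graph()
  classes <- find_parity_classes(g)
  expect_error(compress(g, classes[-1]), "partition")
  other <- find_parity_classes(star_graph())
  expect_error(compress(g, other), "not in graph|partition")
})

test_that("compression_summary reports the decomposition sizes", {
  s <- compression_summary(fig4_graph())
  expect_identical(s[["parity_nodes_removed"]], 2L)
  expect_identical(s[["nodes_retained"]], 3L)
  expect_identical(s[["edges_retained"]], 2L)
})
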