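paper_matrix <- rbind(c(1L, 0L, 0L, -1L), c(-1L, 1L, 0L, 0L),
                      c(0L, -1L, 1L, 0L), c(0L, 0L, -1L, 1L))

test_that("symmetric-ternary encoding reproduces the worked example", {
  expect_identical(encode_symmetric_ternary(paper_matrix)$value, "13698880")
  expect_identical(encode_symmetric_ternary(matrix(0L, 1, 1))$value, "0")
  expect_identical(encode_symmetric_ternary(rbind(1L, -1L))$value, "2")
  expect_error(encode_symmetric_ternary(rbind(c(2L, 0L))), "-1, 0 or 1")
})

test_that("decoding inverts encoding, including from bare decimal values", {
  expect_identical(decode_symmetric_ternary("13698880", 4, 4), paper_matrix)
  expect_identical(decode_symmetric_ternary(13698880, 4, 4), paper_matrix)
  expect_identical(decode_symmetric_ternary(0, 2, 3), matrix(0L, 2, 3))
  expect_identical(decode_symmetric_ternary(2, 2, 1), rbind(1L, -1L))
  # out of range: 3 digits hold at most (3^3 - 1) / 2 = 13
  expect_error(decode_symmetric_ternary(14, 3, 1), "out of range")
  expect_error(decode_symmetric_ternary(-14, 3, 1), "out of range")
})

test_that("encode/decode are exact inverses on random grids up to 5x20", {
  set.seed(99)
  for (i in 1:60) {
    nr <- sample(1:5, 1)
    nc <- sample(1:20, 1)
    m <- matrix(sample(c(-1L, 0L, 1L), nr * nc, replace = TRUE), nr, nc)
    code <- encode_symmetric_ternary(m)
    expect_identical(decode_symmetric_ternary(code), m)
    # round trip through the decimal string as well (exceeds 64-bit range
    # for larger grids, so this exercises the bignum path)
    expect_identical(
      decode_symmetric_ternary(code$value, nr, nc), m)
  }
})

test_that("Code values respect the balanced-ternary magnitude bound", {
  for (seed in 1:15) {
    g <- random_connected_digraph(4, sample(4:10, 1), seed)
    code <- canonical_code(g)
    n_digits <- code$n_rows * code$n_cols
    expect_lte(abs(as.numeric(code$value)), (3^n_digits - 1) / 2)
  }
})

test_that("canonical_code basics: single edge, relabeling, validation", {
  expect_identical(canonical_code(digraph(rbind(c("u", "v"))))$value, "2")
  c1 <- canonical_code(cycle_graph(c("1", "2", "3", "4")))
  c2 <- canonical_code(digraph(rbind(c("1", "3"), c("3", "2"),
                                     c("2", "4"), c("4", "1"))))
  expect_true(c1 == c2)
  expect_error(canonical_code(digraph(rbind(c("a", "b"), c("c", "d")))),
               "connected")
  expect_error(canonical_code(digraph(vertices = "x")), "2 to 8")
})

test_that("canonical_code is invariant under random vertex relabelings", {
  set.seed(7)
  for (i in 1:20) {
    g <- random_connected_digraph(sample(3:6, 1), sample(4:9, 1), i + 50L)
    perm <- sample(g$vertices)
    relab <- stats::setNames(perm, g$vertices)
    em <- edge_matrix(g)
    g2 <- digraph(cbind(unname(relab[em[, 1]]), unname(relab[em[, 2]])),
                  vertices = unname(relab[g$vertices]))
    expect_true(canonical_code(g) == canonical_code(g2))
  }
})

test_that("the 13 connected 3-vertex digraph classes get 13 distinct Codes", {
  graphs <- all_digraphs_k3()
  codes <- vapply(graphs, function(g) canonical_code(g)$value, character(1))
  # oracle partition: group by brute-force isomorphism
  oracle_class <- integer(length(graphs))
  next_id <- 0L
  for (i in seq_along(graphs)) {
    for (j in seq_len(i - 1L)) {
      if (are_isomorphic_bruteforce(graphs[[i]], graphs[[j]])) {
        oracle_class[i] <- oracle_class[j]
        break
      }
    }
    if (oracle_class[i] == 0L) {
      next_id <- next_id + 1L
      oracle_class[i] <- next_id
    }
  }
  expect_identical(next_id, 13L)
  expect_identical(length(unique(codes)), 13L)
  # same partition: code equality iff oracle equality
  expect_identical(as.integer(factor(codes, levels = unique(codes))),
                   as.integer(factor(oracle_class,
                                     levels = unique(oracle_class))))
})

test_that("brute-force isomorphism oracle behaves on known pairs", {
  p <- path2_graph()
  expect_true(are_isomorphic_bruteforce(p, path2_graph(c("3", "2", "1"))))
  expect_false(are_isomorphic_bruteforce(
    p, digraph(rbind(c("1", "2"), c("1", "3")))))
  # directed 3-cycle vs one edge reversed: all 6 bijections fail
  cyc <- cycle_graph(c("1", "2", "3"))
  rev1 <- digraph(rbind(c("1", "2"), c("2", "3"), c("1", "3")))
  expect_false(are_isomorphic_bruteforce(cyc, rev1))
  expect_true(are_isomorphic_bruteforce(cyc, cycle_graph(c("b", "c", "a"))))
})

test_that("canonical Codes agree with igraph's isomorphism test", {
  # third-party cross-check, independent of both package code paths
  to_igraph <- function(g) {
    igraph::graph_from_edgelist(edge_matrix(g), directed = TRUE)
  }
  set.seed(31)
  for (i in 1:40) {
    g1 <- random_connected_digraph(4, sample(3:9, 1), 7000L + i)
    g2 <- random_connected_digraph(4, sample(3:9, 1), 7500L + i)
    expect_identical(
      canonical_code(g1)$value == canonical_code(g2)$value,
      igraph::is_isomorphic_to(to_igraph(g1), to_igraph(g2)))
  }
})

test_that("code exemplars decode to the class they mark", {
  for (g in list(ffl_graph(), cycle_graph(c("1", "2", "3")), star_graph())) {
    code <- canonical_code(g)
    ex <- code_exemplar(code)
    em <- do.call(rbind, strsplit(strsplit(ex, ";")[[1]], "->", fixed = TRUE))
    g2 <- digraph(em)
    expect_true(are_isomorphic_bruteforce(g, g2))
  }
})
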