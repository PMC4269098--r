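# Fixture builders and independent brute-force oracles. Everything here is
# deliberately naive: tests cross-check the package's optimized paths
# against these.

fig4_graph <- function() {
  # decoded from the printed 5x6 incidence matrix of the worked
  # parity-node example: nodes 2 and 4 (and 1 and 3) are parity nodes
  digraph(rbind(c("2", "1"), c("2", "3"), c("4", "3"), c("4", "1"),
                c("5", "2"), c("5", "4")))
}

cycle_graph <- function(labels) {
  n <- length(labels)
  digraph(cbind(labels, labels[c(2:n, 1L)]))
}

star_graph <- function() {
  digraph(rbind(c("h", "a"), c("h", "b"), c("h", "c")))
}

ffl_graph <- function() {
  digraph(rbind(c("a", "b"), c("a", "c"), c("b", "c")))
}

path2_graph <- function(labels = c("1", "2", "3")) {
  digraph(rbind(labels[1:2], labels[2:3]))
}

# all 2^6 digraphs on 3 labeled vertices, optionally connected only
all_digraphs_k3 <- function(connected_only = TRUE) {
  pairs <- rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2))
  out <- list()
  for (mask in 0:63) {
    sel <- bitwAnd(mask, 2^(0:5)) > 0
    if (!any(sel)) next
    g <- digraph(cbind(as.character(pairs[sel, 1]),
                       as.character(pairs[sel, 2])),
                 vertices = c("1", "2", "3"))
    if (!connected_only || motifspace::is_weakly_connected(g)) {
      out[[length(out) + 1L]] <- g
    }
  }
  out
}

# rejection-sample a weakly connected random digraph; m is clamped into
# the feasible (and plausibly connectable) range
random_connected_digraph <- function(n, m, seed) {
  m <- min(max(m, n), n * (n - 1L))
  for (i in 0:99) {
    g <- random_digraph(n, m, seed + 1000L * i)
    if (motifspace::is_weakly_connected(g)) return(g)
  }
  stop("could not draw a connected digraph; raise m")
}

# ORACLE: every size-k subset whose induced subgraph is weakly connected,
# by exhaustive combn filter. Returns sorted "i,j,k" keys.
brute_connected_subsets <- function(g, k) {
  n <- motifspace::vcount(g)
  subs <- utils::combn(n, k)
  keys <- character(0)
  for (col in seq_len(ncol(subs))) {
    vs <- subs[, col]
    sg <- motifspace::induced_subgraph(g, g$vertices[vs])
    if (motifspace::is_weakly_connected(sg)) {
      keys <- c(keys, paste(vs, collapse = ","))
    }
  }
  sort(keys)
}

set_keys <- function(sets) {
  sort(vapply(sets, paste, character(1), collapse = ","))
}

# census comparison helper: identical keys and numerically equal counts
expect_census_equal <- function(a, b, tol = 1e-9) {
  expect_identical(names(a$counts), names(b$counts))
  expect_equal(unname(a$counts), unname(b$counts), tolerance = tol)
}

# random graph with planted twin classes; returns list(graph, classes)
planted_twin_graph <- function(seed) {
  set.seed(seed)
  n <- sample(8:12, 1)
  m <- sample(seq(n, 2L * n), 1)
  g <- random_digraph(n, m, seed)
  n_classes <- sample(1:3, 1)
  spec <- lapply(seq_len(n_classes), function(i) {
    list(size = sample(2:5, 1),
         kind = sample(c("false_twin", "true_twin"), 1))
  })
  plant_twins(g, spec, seed + 1L)
}

# swap the labels of two vertices in place (identity on everything else)
swap_labels <- function(g, u, v) {
  relab <- stats::setNames(g$vertices, g$vertices)
  relab[[u]] <- v
  relab[[v]] <- u
  em <- motifspace::edge_matrix(g)
  digraph(cbind(unname(relab[em[, 1]]), unname(relab[em[, 2]])),
          vertices = unname(relab[g$vertices]))
}
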