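#' Uniform random simple digraph
#'
#' Exactly `m` directed edges drawn uniformly without replacement from the
#' `n * (n - 1)` non-loop ordered pairs; vertices are labeled `"1".."n"` in
#' order. A pure function of `(n, m, seed)`.
#'
#' @param n number of vertices.
#' @param m number of edges, `0 <= m <= n * (n - 1)`.
#' @param seed integer seed (mandatory: generators are part of the test
#'   contract and must be bitwise reproducible).
#' @return a `digraph`.
#' @export
random_digraph <- function(n, m, seed) {
  n <- as.integer(n)
  m <- as.integer(m)
  if (n < 1L || m < 0L || m > n * (n - 1L)) {
    stop("infeasible (n, m) for a simple digraph")
  }
  pairs <- .with_seed(seed, sample.int(n * (n - 1L), m))
  # pair index -> (u, v), skipping the diagonal
  u <- (pairs - 1L) %/% (n - 1L) + 1L
  r <- (pairs - 1L) %% (n - 1L) + 1L
  v <- ifelse(r >= u, r + 1L, r)
  digraph(cbind(as.character(u), as.character(v)),
          vertices = as.character(seq_len(n)))
}

#' Plant structural twin classes into a graph
#'
#' For each requested class, adds `size` fresh vertices sharing one
#' randomly drawn external neighborhood (an out-set and an in-set sampled
#' from the pre-existing vertices), with intra-class adjacency per kind:
#' none for `false_twin`, all ordered pairs for `true_twin`. The planted
#' members are exact structural twins by construction, so
#' [find_parity_classes()] in structural mode must recover each planted
#' class as a subset of one reported class.
#'
#' @param g background `digraph` (its vertices supply the neighborhoods).
#' @param class_spec list of `c(size, kind)` pairs, e.g.
#'   `list(list(size = 3, kind = "false_twin"))`.
#' @param seed integer seed.
#' @return list with `graph` (the augmented `digraph`) and `classes`
#'   (ground-truth label sets, one character vector per planted class).
#' @export
plant_twins <- function(g, class_spec, seed) {
  .check_digraph(g)
  base <- g$vertices
  if (length(base) == 0L) stop("background graph needs at least one vertex")
  edges <- edge_matrix(g)
  planted <- list()
  .with_seed(seed, {
    for (ci in seq_along(class_spec)) {
      cs <- class_spec[[ci]]
      size <- as.integer(cs$size %||% cs[[1L]])
      kind <- as.character(cs$kind %||% cs[[2L]])
      if (size < 2L) stop("planted twin classes need size >= 2")
      if (!kind %in% c("false_twin", "true_twin")) {
        stop("kind must be 'false_twin' or 'true_twin'")
      }
      labs <- paste0("tw", ci, "_", seq_len(size))
      n_out <- sample.int(length(base), 1L)
      n_in <- sample.int(length(base), 1L)
      outs <- sample(base, n_out)
      ins <- sample(base, n_in)
      for (lab in labs) {
        if (length(outs)) edges <- rbind(edges, cbind(lab, outs))
        if (length(ins)) edges <- rbind(edges, cbind(ins, lab))
      }
      if (kind == "true_twin") {
        pr <- expand.grid(a = labs, b = labs, stringsAsFactors = FALSE)
        pr <- pr[pr$a != pr$b, , drop = FALSE]
        edges <- rbind(edges, cbind(pr$a, pr$b))
      }
      planted[[ci]] <- labs
    }
  })
  list(graph = digraph(edges, vertices = c(base,
                                           unlist(planted, use.names = FALSE))),
       classes = planted)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plant vertex-disjoint motif copies
#'
#' Inserts `n_copies` disjoint copies of `pattern` on fresh vertices. The
#' background is the input graph itself; optional extra background edges
#' connect only non-planted vertices, so the census count of the pattern's
#' Code provably stays at least `n_copies` (disjoint copies cannot be
#' destroyed or double-counted, and no cross edges are ever added to the
#' planted vertices).
#'
#' @param g background `digraph`.
#' @param pattern connected `digraph` with 2..5 vertices.
#' @param n_copies number of disjoint copies to insert.
#' @param seed integer seed (used for the optional extra background edges).
#' @param extra_background additional random edges among the background
#'   vertices (default 0; the background graph usually already carries its
#'   own edges).
#' @return a `digraph`.
#' @export
plant_motif <- function(g, pattern, n_copies, seed, extra_background = 0L) {
  .check_digraph(g)
  .check_digraph(pattern)
  if (vcount(pattern) < 2L || vcount(pattern) > 5L ||
      !is_weakly_connected(pattern)) {
    stop("pattern must be a connected digraph with 2..5 vertices")
  }
  n_copies <- as.integer(n_copies)
  edges <- edge_matrix(g)
  verts <- g$vertices
  pe <- edge_matrix(pattern)
  for (i in seq_len(n_copies)) {
    relab <- stats::setNames(paste0("m", i, "_", seq_len(vcount(pattern))),
                             pattern$vertices)
    edges <- rbind(edges, cbind(relab[pe[, 1L]], relab[pe[, 2L]]))
    verts <- c(verts, unname(relab))
  }
  extra_background <- as.integer(extra_background)
  if (extra_background > 0L) {
    nb <- length(g$vertices)
    have <- paste0(edges[, 1L], "\r", edges[, 2L])
    new_edges <- .with_seed(seed, {
      cand <- expand.grid(u = g$vertices, v = g$vertices,
                          stringsAsFactors = FALSE)
      cand <- cand[cand$u != cand$v, , drop = FALSE]
      cand <- cand[!paste0(cand$u, "\r", cand$v) %in% have, , drop = FALSE]
      take <- sample.int(nrow(cand), min(extra_background, nrow(cand)))
      as.matrix(cand[take, , drop = FALSE])
    })
    if (nrow(new_edges) > 0L) edges <- rbind(edges, new_edges)
    if (nb == 0L && extra_background > 0L) {
      warning("no background vertices; extra_background ignored")
    }
  }
  digraph(edges, vertices = verts)
}
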