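#' Construct a directed simple graph
#'
#' The data model every stage of the motif pipeline operates on: a labeled
#' simple digraph. Vertex labels are opaque strings; the order in which
#' vertices first appear is the "mark number" used to break every ordering
#' tie downstream (compression representatives, enumeration order).
#'
#' Self-loops are a hard error because the vertex-edge incidence
#' representation at the heart of the Code machinery cannot express them,
#' and silently dropping them would corrupt degree sequences. Duplicate
#' edges are collapsed with a warning.
#'
#' @param edges two-column character matrix (or coercible data.frame) of
#'   source, target labels; may have zero rows.
#' @param vertices optional character vector fixing the vertex order and/or
#'   adding isolated vertices; defaults to first-appearance order over the
#'   edge list.
#' @return an object of class `digraph` with fields `vertices` (character),
#'   `from`, `to` (integer indices into `vertices`).
#' @examples
#' g <- digraph(rbind(c("a", "b"), c("b", "c")))
#' vcount(g); ecount(g)
#' @export
digraph <- function(edges = NULL, vertices = NULL) {
  if (is.null(edges)) {
    edges <- matrix(character(0), ncol = 2L)
  }
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
  if (!is.matrix(edges) || ncol(edges) < 2L) {
    stop("edges must be a two-column matrix of source, target labels")
  }
  storage.mode(edges) <- "character"
  edges <- edges[, 1:2, drop = FALSE]
  if (any(edges[, 1] == edges[, 2])) {
    bad <- which(edges[, 1] == edges[, 2])[1L]
    stop("self-loop on vertex ", sQuote(edges[bad, 1]),
         ": the incidence representation cannot encode self-loops")
  }
  appear <- as.vector(t(edges))
  verts <- unique(c(as.character(vertices), appear))
  if (anyNA(verts) || any(!nzchar(verts))) {
    stop("vertex labels must be non-empty, non-NA strings")
  }
  from <- match(edges[, 1], verts)
  to <- match(edges[, 2], verts)
  key <- paste0(from, "\r", to)
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate edge(s) collapsed")
    from <- from[!dup]
    to <- to[!dup]
  }
  structure(list(vertices = verts, from = as.integer(from),
                 to = as.integer(to)),
            class = "digraph")
}

#' @export
print.digraph <- function(x, ...) {
  cat("digraph: ", vcount(x), " vertices, ", ecount(x), " edges\n", sep = "")
  if (ecount(x) > 0L) {
    show <- utils::head(paste0(x$vertices[x$from], " -> ", x$vertices[x$to]), 10L)
    cat("  ", paste(show, collapse = ", "),
        if (ecount(x) > 10L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Number of vertices / edges
#' @param g a `digraph`
#' @return integer count.
#' @rdname digraph-size
#' @export
vcount <- function(g) length(g$vertices)

#' @rdname digraph-size
#' @export
ecount <- function(g) length(g$from)

#' Edge list of a digraph as a character matrix
#' @param g a `digraph`
#' @return two-column character matrix (source, target), one row per edge.
#' @export
edge_matrix <- function(g) {
  cbind(source = g$vertices[g$from], target = g$vertices[g$to])
}

#' Exact equality of labeled digraphs
#'
#' Same vertex set, same edge set (labels compared as sets; order ignored).
#' @param g1,g2 `digraph` objects
#' @return logical scalar.
#' @export
graph_identical <- function(g1, g2) {
  setequal(g1$vertices, g2$vertices) &&
    ecount(g1) == ecount(g2) &&
    setequal(paste0(g1$vertices[g1$from], "\r", g1$vertices[g1$to]),
             paste0(g2$vertices[g2$from], "\r", g2$vertices[g2$to]))
}

.check_digraph <- function(g) {
  if (!inherits(g, "digraph")) stop("expected a digraph object")
  g
}

.vertex_index <- function(g, v) {
  idx <- match(as.character(v), g$vertices)
  if (anyNA(idx)) {
    stop("unknown vertex label(s): ",
         paste(sQuote(as.character(v)[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Read a directed edge list from text
#'
#' Parses the plain-text format used by published transcription-network
#' collections: one edge per line, `source<ws>target`, optional extra tokens
#' (edge weights/signs) that are ignored with a note, `#` comment lines and
#' blank lines skipped. Vertices are returned in first-appearance order,
#' which downstream code uses as the tie-breaking "mark number".
#'
#' @param con a file path, connection, or character vector of lines.
#' @param comment_prefix lines starting with this prefix are skipped.
#' @param delimiter regular expression splitting tokens (default: any
#'   whitespace run).
#' @return a [digraph()].
#' @seealso [write_edge_list()]
#' @export
read_edge_list <- function(con, comment_prefix = "#", delimiter = "[ \t]+") {
  lines <- if (is.character(con) && (length(con) > 1L || !file.exists(con))) {
    con
  } else {
    readLines(con, warn = FALSE)
  }
  keep <- !grepl("^[ \t]*$", lines) &
    !startsWith(trimws(lines), comment_prefix)
  lineno <- which(keep)
  lines <- trimws(lines[keep])
  if (length(lines) == 0L) return(digraph())
  toks <- strsplit(lines, delimiter)
  nt <- lengths(toks)
  if (any(nt < 2L)) {
    stop("line ", lineno[which(nt < 2L)[1L]],
         ": fewer than 2 tokens (need source and target)")
  }
  src <- vapply(toks, `[[`, character(1), 1L)
  dst <- vapply(toks, `[[`, character(1), 2L)
  if (any(src == dst)) {
    stop("self-loop at line ", lineno[which(src == dst)[1L]])
  }
  if (any(nt > 2L)) {
    message("note: ", sum(nt > 2L),
            " line(s) carried extra tokens (ignored)")
  }
  dup <- duplicated(paste0(src, "\r", dst))
  if (any(dup)) {
    warning(sum(dup), " duplicate edge line(s) collapsed (first kept: line ",
            lineno[which(dup)[1L]], ")")
    src <- src[!dup]
    dst <- dst[!dup]
  }
  digraph(cbind(src, dst))
}

#' Write a digraph as a plain-text edge list
#'
#' Emits the same dialect [read_edge_list()] parses: one `source target`
#' line per edge in input order, LF endings. Round-trips exactly for graphs
#' without isolated vertices (isolates cannot be expressed by an edge list
#' and are dropped with a warning).
#'
#' @param g a `digraph`
#' @param path file path or connection; `NULL` returns the lines invisibly
#'   without writing.
#' @return the character vector of lines, invisibly.
#' @export
write_edge_list <- function(g, path = NULL) {
  .check_digraph(g)
  touched <- unique(c(g$from, g$to))
  if (length(touched) < vcount(g)) {
    warning(vcount(g) - length(touched),
            " isolated vertex/vertices not representable in an edge list")
  }
  lines <- paste(g$vertices[g$from], g$vertices[g$to])
  if (!is.null(path)) writeLines(lines, path, sep = "\n")
  invisible(lines)
}

#' Vertex-edge incidence matrix M(G)
#'
#' The storage representation of the method: rows are vertices, columns are
#' edges, entry +1 where the row vertex is the column edge's source, -1
#' where it is the target, 0 elsewhere. Every column therefore holds exactly
#' one +1 and one -1, the count of +1 entries equals the edge count, and the
#' algebraic sum of all entries is zero.
#'
#' @param g a `digraph`
#' @param vertex_order permutation of `g$vertices` giving the row order.
#' @param edge_order permutation of the edges, as a two-column label matrix
#'   or an integer permutation of edge indices; default input order.
#' @return integer matrix with vertex labels as rownames and `u->v` edge
#'   identifiers as colnames.
#' @examples
#' g <- digraph(rbind(c("1","3"), c("3","2"), c("2","4"), c("4","1")))
#' incidence_matrix(g, vertex_order = c("1","3","2","4"))
#' @export
incidence_matrix <- function(g, vertex_order = g$vertices, edge_order = NULL) {
  .check_digraph(g)
  vertex_order <- as.character(vertex_order)
  if (length(vertex_order) != vcount(g) ||
      !setequal(vertex_order, g$vertices) ||
      anyDuplicated(vertex_order)) {
    stop("vertex_order must be a permutation of the graph's vertices")
  }
  m <- ecount(g)
  if (is.null(edge_order)) {
    eidx <- seq_len(m)
  } else if (is.numeric(edge_order)) {
    eidx <- as.integer(edge_order)
    if (!identical(sort(eidx), seq_len(m))) {
      stop("edge_order must be a permutation of edge indices")
    }
  } else {
    em <- as.matrix(edge_order)
    key <- paste0(g$vertices[g$from], "\r", g$vertices[g$to])
    eidx <- match(paste0(em[, 1], "\r", em[, 2]), key)
    if (anyNA(eidx) || length(eidx) != m || anyDuplicated(eidx)) {
      stop("edge_order must be a permutation of the graph's edges")
    }
  }
  pos <- match(g$vertices, vertex_order)
  out <- matrix(0L, nrow = vcount(g), ncol = m,
                dimnames = list(vertex_order,
                                paste0(g$vertices[g$from[eidx]], "->",
                                       g$vertices[g$to[eidx]])))
  if (m > 0L) {
    cols <- seq_len(m)
    out[cbind(pos[g$from[eidx]], cols)] <- 1L
    out[cbind(pos[g$to[eidx]], cols)] <- -1L
  }
  out
}

#' Induced subgraph on a vertex subset
#'
#' Keeps every edge of `g` with both endpoints in `vertex_set` (induced
#' semantics -- the census convention throughout). Relative vertex order is
#' preserved.
#'
#' @param g a `digraph`
#' @param vertex_set character vector of vertex labels (or integer indices).
#' @return a `digraph`.
#' @export
induced_subgraph <- function(g, vertex_set) {
  .check_digraph(g)
  idx <- if (is.numeric(vertex_set)) {
    ii <- as.integer(vertex_set)
    if (any(ii < 1L | ii > vcount(g))) stop("vertex index out of range")
    ii
  } else {
    .vertex_index(g, vertex_set)
  }
  idx <- sort(unique(idx))
  inside <- logical(vcount(g))
  inside[idx] <- TRUE
  keep <- inside[g$from] & inside[g$to]
  digraph(cbind(g$vertices[g$from[keep]], g$vertices[g$to[keep]]),
          vertices = g$vertices[idx])
}

#' In/out degree pair of a vertex
#'
#' Parity (twin) candidates are grouped by this pair: two vertices qualify
#' under the degree definition iff their `(d_in, d_out)` coincide.
#'
#' @param g a `digraph`
#' @param v vertex label.
#' @return named integer vector `c(d_in = ..., d_out = ...)`.
#' @export
degree_pair <- function(g, v) {
  .check_digraph(g)
  idx <- .vertex_index(g, v)
  c(d_in = sum(g$to == idx), d_out = sum(g$from == idx))
}

#' All degree pairs at once
#' @param g a `digraph`
#' @return integer matrix, one row per vertex, columns `d_in`, `d_out`.
#' @export
degree_pairs <- function(g) {
  .check_digraph(g)
  n <- vcount(g)
  cbind(d_in = tabulate(g$to, nbins = n),
        d_out = tabulate(g$from, nbins = n))
}

#' Weak connectivity
#'
#' TRUE iff the underlying undirected graph is connected; a single vertex
#' counts as connected. The empty graph is an error (connectivity of nothing
#' is undefined and always indicates a caller bug here).
#'
#' @param g a `digraph`
#' @return logical scalar.
#' @export
is_weakly_connected <- function(g) {
  .check_digraph(g)
  n <- vcount(g)
  if (n == 0L) stop("empty graph: weak connectivity undefined")
  if (n == 1L) return(TRUE)
  nbr <- .undirected_adjacency(g)
  seen <- logical(n)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nx <- nbr[[v]]
    nx <- nx[!seen[nx]]
    seen[nx] <- TRUE
    stack <- c(stack, nx)
  }
  all(seen)
}

# sorted undirected adjacency lists (union of in- and out-neighbors)
.undirected_adjacency <- function(g) {
  n <- vcount(g)
  ends <- c(g$from, g$to)
  other <- c(g$to, g$from)
  lapply(split(other, factor(ends, levels = seq_len(n))),
         function(x) sort(unique(x)))
}

# n x n logical adjacency matrix (adj[u, v] == TRUE iff edge u -> v)
.adjacency_matrix <- function(g) {
  n <- vcount(g)
  a <- matrix(FALSE, n, n)
  if (ecount(g) > 0L) a[cbind(g$from, g$to)] <- TRUE
  a
}
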