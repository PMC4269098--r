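#' Find parity (twin) vertex classes
#'
#' Groups vertices declared interchangeable before the subgraph search.
#' Two modes:
#'
#' * `"structural"` (default): maximal sets of vertices with identical
#'   out-neighbor and in-neighbor sets outside the class and uniform
#'   intra-class adjacency -- either no edges among members (*false twins*)
#'   or all ordered pairs mutually connected (*true twins*). Exchanging two
#'   such vertices is a graph automorphism, which is what makes compression
#'   count-safe.
#' * `"degree"`: the frequency partition by exact `(d_in, d_out)`. This is
#'   the looser letter of the parity-node definition; it does **not**
#'   guarantee interchangeability and is count-unsafe for census expansion
#'   (provided for fidelity, flagged in results).
#'
#' Classes are returned for every vertex (singletons included), ordered by
#' their representative -- the minimum input-order member ("minimum mark
#' number"). When a vertex qualifies both as a false twin of one set and a
#' true twin of another, false-twin classes claim vertices first, in
#' representative order (a deterministic greedy split of mixed classes).
#'
#' @param g a `digraph`
#' @param mode `"structural"` or `"degree"`.
#' @return list of `parity_class` objects: `members` (labels, input order),
#'   `representative`, `degree` (`c(d_in, d_out)`), `twin_kind`
#'   (`"false_twin"`, `"true_twin"`, or `"mixed"` in degree mode).
#' @examples
#' g <- digraph(rbind(c("2","1"), c("2","3"), c("4","3"), c("4","1"),
#'                    c("5","2"), c("5","4")))
#' find_parity_classes(g)   # {2,4} and {1,3} are parity classes
#' @export
find_parity_classes <- function(g, mode = c("structural", "degree")) {
  .check_digraph(g)
  mode <- match.arg(mode)
  n <- vcount(g)
  if (n == 0L) return(list())
  deg <- degree_pairs(g)
  adj <- .adjacency_matrix(g)

  mk_class <- function(members_idx, kind) {
    members_idx <- sort(members_idx)
    structure(list(members = g$vertices[members_idx],
                   member_idx = members_idx,
                   representative = g$vertices[members_idx[1L]],
                   degree = c(d_in = unname(deg[members_idx[1L], 1L]),
                              d_out = unname(deg[members_idx[1L], 2L])),
                   twin_kind = kind),
              class = "parity_class")
  }

  if (mode == "degree") {
    groups <- split(seq_len(n), paste0(deg[, 1L], ",", deg[, 2L]))
    classes <- lapply(groups, function(idx) {
      kind <- if (length(idx) == 1L) "false_twin"
      else {
        sub <- adj[idx, idx, drop = FALSE]
        diag(sub) <- NA
        off <- sub[!is.na(sub)]
        if (all(!off)) "false_twin" else if (all(off)) "true_twin" else "mixed"
      }
      mk_class(idx, kind)
    })
  } else {
    outs <- lapply(seq_len(n), function(v) which(adj[v, ]))
    ins <- lapply(seq_len(n), function(v) which(adj[, v]))
    open_key <- vapply(seq_len(n), function(v) {
      paste(paste(outs[[v]], collapse = ","),
            paste(ins[[v]], collapse = ","), sep = "|")
    }, character(1))
    closed_key <- vapply(seq_len(n), function(v) {
      paste(paste(sort(c(outs[[v]], v)), collapse = ","),
            paste(sort(c(ins[[v]], v)), collapse = ","), sep = "|")
    }, character(1))
    # identical open neighborhoods imply no intra-class edges (an edge would
    # force a self-loop); identical closed neighborhoods imply full mutual
    # intra-class connection. Greedy claim: false groups first.
    assigned <- logical(n)
    classes <- list()
    for (grp in .groups_by_min(open_key, n)) {
      if (length(grp) >= 2L) {
        classes[[length(classes) + 1L]] <- mk_class(grp, "false_twin")
        assigned[grp] <- TRUE
      }
    }
    for (grp in .groups_by_min(closed_key, n)) {
      grp <- grp[!assigned[grp]]
      if (length(grp) >= 2L) {
        classes[[length(classes) + 1L]] <- mk_class(grp, "true_twin")
        assigned[grp] <- TRUE
      }
    }
    for (v in which(!assigned)) {
      classes[[length(classes) + 1L]] <- mk_class(v, "false_twin")
    }
  }
  classes <- unname(classes)
  classes[order(vapply(classes, function(cl) cl$member_idx[1L], integer(1)))]
}

# split indices 1..n by key, groups ordered by their minimum member
.groups_by_min <- function(key, n) {
  groups <- split(seq_len(n), key)
  groups[order(vapply(groups, min, integer(1)))]
}

#' @export
print.parity_class <- function(x, ...) {
  cat("parity_class {", paste(x$members, collapse = ", "), "} rep=",
      x$representative, " d_in=", x$degree[["d_in"]],
      " d_out=", x$degree[["d_out"]], " ", x$twin_kind, "\n", sep = "")
  invisible(x)
}

#' Compress a graph by removing redundant parity-class members
#'
#' From every parity class, all members but the representative (minimum
#' input order) are removed. The result is the three-part decomposition:
#' `g_r`, the retained graph (representatives plus singletons and the edges
#' among them); `g_p`, the removed parity vertices; `g_cv`, the original
#' edges incident to at least one removed vertex. Vertices and edges of
#' `g_r` together with `g_p` and `g_cv` partition the original graph
#' exactly.
#'
#' @param g a `digraph`
#' @param classes result of [find_parity_classes()] on `g` (recomputed with
#'   the default mode when omitted).
#' @return an object of class `compressed_graph`: `g_r`, `g_p` (character),
#'   `g_cv` (two-column edge matrix), `classes`, `multiplicity` (named
#'   integer, representative -> class size), `original` (the input graph),
#'   `mode_hint` (`"structural"` unless any class is `"mixed"`).
#' @export
compress <- function(g, classes = find_parity_classes(g)) {
  .check_digraph(g)
  n <- vcount(g)
  seen <- integer(0)
  for (cl in classes) {
    if (!inherits(cl, "parity_class")) stop("classes must be parity_class objects")
    idx <- match(cl$members, g$vertices)
    if (anyNA(idx)) stop("class member not in graph: ",
                         paste(cl$members[is.na(idx)], collapse = ", "))
    seen <- c(seen, idx)
  }
  if (length(seen) != n || anyDuplicated(seen)) {
    stop("classes must partition the graph's vertices")
  }
  reps <- vapply(classes, function(cl) cl$representative, character(1))
  removed <- unlist(lapply(classes, function(cl) {
    setdiff(cl$members, cl$representative)
  }))
  keep_idx <- sort(match(setdiff(g$vertices, removed), g$vertices))
  g_r <- induced_subgraph(g, g$vertices[keep_idx])
  rm_set <- g$vertices %in% removed
  cv <- rm_set[g$from] | rm_set[g$to]
  sizes <- vapply(classes, function(cl) length(cl$members), integer(1))
  structure(list(
    g_r = g_r,
    g_p = g$vertices[sort(match(removed, g$vertices))],
    g_cv = edge_matrix(g)[cv, , drop = FALSE],
    classes = classes,
    multiplicity = stats::setNames(sizes, reps),
    original = g,
    mode_hint = if (any(vapply(classes, function(cl) cl$twin_kind,
                               character(1)) == "mixed"))
      "degree" else "structural"
  ), class = "compressed_graph")
}

#' @export
print.compressed_graph <- function(x, ...) {
  cat("compressed_graph: ", vcount(x$original), " -> ", vcount(x$g_r),
      " vertices, ", ecount(x$original), " -> ", ecount(x$g_r), " edges; ",
      length(x$g_p), " parity node(s) removed\n", sep = "")
  invisible(x)
}

#' Node/edge bookkeeping of a compression
#'
#' Summary used to report compression on real networks: how many parity
#' nodes were removed and what remains.
#'
#' @param g a `digraph` (or a ready `compressed_graph`).
#' @return named integer vector: `nodes`, `edges`, `parity_nodes_removed`,
#'   `nodes_retained`, `edges_retained`.
#' @export
compression_summary <- function(g) {
  cg <- if (inherits(g, "compressed_graph")) g else compress(g)
  c(nodes = vcount(cg$original), edges = ecount(cg$original),
    parity_nodes_removed = length(cg$g_p),
    nodes_retained = vcount(cg$g_r), edges_retained = ecount(cg$g_r))
}

#' Multiplicity-aware census of a compressed graph
#'
#' Enumerates connected induced k-patterns in which each parity class may
#' contribute up to `min(size, k)` interchangeable members. Implementation:
#' the first `min(size, k)` members of every class are kept ("clones"), the
#' induced subgraph on kept vertices is enumerated exhaustively, and raw
#' counts are divided by `prod(choose(kept_c, r_c))` -- clones of a class
#' are interchangeable, so each distinct multiset embedding (pattern plus
#' per-class usage `r_c`) was seen exactly that many times.
#'
#' @param cg a `compressed_graph`.
#' @param k subgraph size.
#' @return object of class `compressed_census`: `k` and `entries`, a list
#'   keyed by signature with fields `code`, `usage` (named integer, class
#'   representative -> r_c for classes used beyond none), `n_embeddings`
#'   (distinct multiset embeddings).
#' @export
compressed_census <- function(cg, k) {
  if (!inherits(cg, "compressed_graph")) stop("expected a compressed_graph")
  if (cg$mode_hint != "structural") {
    warning("degree-mode parity classes are not structurally ",
            "interchangeable; expanded counts are not exact")
  }
  g <- cg$original
  k <- as.integer(k)
  kept <- unlist(lapply(cg$classes, function(cl) {
    cl$member_idx[seq_len(min(length(cl$member_idx), k))]
  }))
  kept <- sort(kept)
  gk <- induced_subgraph(g, g$vertices[kept])
  # class id and true/kept size per kept-graph vertex
  class_id <- integer(vcount(gk))
  size_all <- kept_n <- integer(length(cg$classes))
  for (ci in seq_along(cg$classes)) {
    cl <- cg$classes[[ci]]
    size_all[ci] <- length(cl$member_idx)
    idx <- match(cl$members, gk$vertices)
    idx <- idx[!is.na(idx)]
    kept_n[ci] <- length(idx)
    # singleton classes carry no multiplicity; keep them out of usage keys
    if (size_all[ci] >= 2L) class_id[idx] <- ci
  }
  adj <- .adjacency_matrix(gk)
  acc <- new.env(parent = emptyenv())
  .esu(gk, k, NULL, NULL, function(vs) {
    sig <- .adjacency_signature(adj[vs, vs, drop = FALSE])
    usage <- tabulate(class_id[vs], nbins = length(cg$classes))
    ukey <- paste(which(usage > 0L), usage[usage > 0L],
                  sep = ":", collapse = ",")
    key <- paste0(sig, "#", ukey)
    prev <- acc[[key]]
    if (is.null(prev)) {
      acc[[key]] <- list(sig = sig, usage = usage, raw = 1)
    } else {
      prev$raw <- prev$raw + 1
      acc[[key]] <- prev
    }
  })
  entries <- lapply(ls(acc, sorted = TRUE), function(key) {
    e <- acc[[key]]
    used <- which(e$usage > 0L)
    dup <- prod(choose(kept_n[used], e$usage[used]))
    kk <- as.integer(sqrt(nchar(e$sig)))
    adjs <- matrix(charToRaw(e$sig) == as.raw(49L), kk, kk)
    list(code = .canonical_code_adj(adjs),
         usage = stats::setNames(e$usage[used],
                                 vapply(cg$classes[used],
                                        function(cl) cl$representative,
                                        character(1))),
         used = used,
         n_embeddings = e$raw / dup)
  })
  structure(list(k = k, entries = entries, size_all = size_all,
                 kept_n = kept_n),
            class = "compressed_census")
}

#' Expand a compressed census to full-graph counts
#'
#' Each distinct multiset embedding that uses `r_c` members of class `c`
#' stands for `prod(choose(size_c, r_c))` embeddings of the uncompressed
#' graph (any `r_c`-subset of the class yields the same pattern, because
#' class members are interchangeable). Summing those weights per canonical
#' Code reproduces the direct census exactly in structural mode.
#'
#' @param cc a `compressed_census` from [compressed_census()].
#' @param k subgraph size (must match `cc$k`).
#' @return a `subgraph_census` equal to `subgraph_census(original, k)`.
#' @export
expand_census <- function(cc, k) {
  if (!inherits(cc, "compressed_census")) stop("expected a compressed_census")
  if (as.integer(k) != cc$k) stop("k does not match the compressed census")
  counts <- numeric(0)
  codes <- list()
  for (e in cc$entries) {
    w <- e$n_embeddings * prod(choose(cc$size_all[e$used],
                                      e$usage[seq_along(e$used)]))
    key <- .code_key(e$code)
    counts[key] <- (if (is.na(counts[key])) 0 else counts[key]) + w
    if (is.null(codes[[key]])) codes[[key]] <- e$code
  }
  .new_census(cc$k, counts, codes)
}
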