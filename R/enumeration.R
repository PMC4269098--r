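#' Enumerate connected induced k-subgraphs (ESU backtracking)
#'
#' Anchor-and-extend backtracking over the undirected skeleton: each vertex
#' in turn anchors a search restricted to higher-numbered exclusive
#' neighbors, so every vertex set whose induced subgraph is weakly connected
#' is produced exactly once, in a deterministic order (ascending input
#' order). With `sample_probs`, each depth-d extension is explored with
#' probability `sample_probs[d]` (the RAND-ESU scheme) and every yielded set
#' carries weight `1 / prod(sample_probs)`, making weighted counts unbiased
#' estimates of the exact counts.
#'
#' @param g a `digraph`
#' @param k subgraph size, `2 <= k <= min(vcount(g), 8)`.
#' @param sample_probs optional numeric vector of length `k`, entries in
#'   (0, 1]; omit for exhaustive enumeration.
#' @param seed integer seed for the sampled mode (required there).
#' @return list of integer vertex-index vectors (sorted within each set),
#'   with attribute `weight` (scalar weight common to all yielded sets; 1 in
#'   exact mode).
#' @export
enumerate_connected_subsets <- function(g, k, sample_probs = NULL,
                                        seed = NULL) {
  out <- new.env(parent = emptyenv())
  out$sets <- vector("list", 64L)
  out$n <- 0L
  .esu(g, k, sample_probs, seed, function(vs) {
    out$n <- out$n + 1L
    if (out$n > length(out$sets)) {
      out$sets <- c(out$sets, vector("list", length(out$sets)))
    }
    out$sets[[out$n]] <- vs
  })
  sets <- out$sets[seq_len(out$n)]
  attr(sets, "weight") <- if (is.null(sample_probs)) 1 else
    1 / prod(sample_probs)
  sets
}

# Core ESU walk; calls visit(sorted_vertex_indices) per yielded set.
.esu <- function(g, k, sample_probs, seed, visit) {
  .check_digraph(g)
  k <- as.integer(k)
  n <- vcount(g)
  if (k < 2L || k > 8L || k > n) {
    stop("k must satisfy 2 <= k <= min(vcount(g), 8)")
  }
  sampled <- !is.null(sample_probs)
  if (sampled) {
    sample_probs <- as.numeric(sample_probs)
    if (length(sample_probs) != k ||
        any(sample_probs <= 0 | sample_probs > 1)) {
      stop("sample_probs must have length k with entries in (0, 1]")
    }
    if (is.null(seed)) stop("sampled enumeration requires a seed")
  }
  nbr <- .undirected_adjacency(g)
  take <- if (sampled) {
    function(depth) sample_probs[depth] >= 1 ||
      stats::runif(1L) < sample_probs[depth]
  } else {
    function(depth) TRUE
  }

  extend <- function(sub, ext, anchor, nbhd) {
    depth <- length(sub) + 1L
    if (depth == k) {
      for (w in ext) if (take(k)) visit(sort(c(sub, w)))
      return(invisible())
    }
    while (length(ext) > 0L) {
      w <- ext[1L]
      ext <- ext[-1L]
      if (!take(depth)) next
      nw <- nbr[[w]]
      fresh <- nw[nw > anchor & !nbhd[nw]]
      nbhd2 <- nbhd
      nbhd2[fresh] <- TRUE
      extend(c(sub, w), c(ext, fresh), anchor, nbhd2)
    }
  }

  run <- function() {
    for (v in seq_len(n)) {
      if (!take(1L)) next
      nv <- nbr[[v]]
      ext <- nv[nv > v]
      nbhd <- logical(n)
      nbhd[c(v, nv)] <- TRUE
      extend(v, ext, v, nbhd)
    }
  }
  if (sampled) .with_seed(seed, run()) else run()
  invisible()
}

# Evaluate expr under a temporary RNG state, restoring the caller's.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

.new_census <- function(k, counts, codes) {
  o <- order(names(counts))
  structure(list(k = as.integer(k), counts = counts[o], codes = codes[o],
                 total = sum(counts)),
            class = "subgraph_census")
}

#' @export
print.subgraph_census <- function(x, ...) {
  cat("subgraph census, k = ", x$k, ": ", length(x$counts),
      " class(es), total ", format(x$total), "\n", sep = "")
  for (key in names(x$counts)) {
    cat("  ", x$codes[[key]]$value, "  ", format(x$counts[[key]]),
        "  ", code_exemplar(x$codes[[key]]), "\n", sep = "")
  }
  invisible(x)
}

#' Census of connected induced k-subgraphs by canonical Code
#'
#' Runs the enumeration and tallies each yielded set under the canonical
#' Code of its induced subgraph. Canonicalization is memoized on the induced
#' adjacency pattern, so the cost is dominated by the enumeration itself.
#'
#' @inheritParams enumerate_connected_subsets
#' @return an object of class `subgraph_census`: `k`, `counts` (named
#'   numeric, keys `"<value>@<rows>x<cols>"`), `codes` (named list of
#'   [ternary_code()] objects), `total`. Counts are integers in exact mode
#'   and inverse-probability weights in sampled mode.
#' @examples
#' g <- digraph(rbind(c("1","2"), c("2","3"), c("3","4"), c("4","1")))
#' subgraph_census(g, 3)   # 4 copies of the 2-edge directed path
#' @export
subgraph_census <- function(g, k, sample_probs = NULL, seed = NULL) {
  adj <- .adjacency_matrix(g)
  w <- if (is.null(sample_probs)) 1 else 1 / prod(sample_probs)
  acc <- new.env(parent = emptyenv())
  .esu(g, k, sample_probs, seed, function(vs) {
    sig <- .adjacency_signature(adj[vs, vs, drop = FALSE])
    prev <- acc[[sig]]
    acc[[sig]] <- if (is.null(prev)) w else prev + w
  })
  .census_from_signatures(acc, k)
}

# fold a signature -> weight environment into a canonical-Code census
.census_from_signatures <- function(acc, k) {
  sigs <- ls(acc, sorted = FALSE)
  counts <- numeric(0)
  codes <- list()
  for (sig in sigs) {
    kk <- as.integer(sqrt(nchar(sig)))
    adj <- matrix(charToRaw(sig) == as.raw(49L), kk, kk)
    code <- .canonical_code_adj(adj)
    key <- .code_key(code)
    counts[key] <- (if (is.na(counts[key])) 0 else counts[key]) + acc[[sig]]
    if (is.null(codes[[key]])) codes[[key]] <- code
  }
  .new_census(k, counts, codes)
}

#' Census over a compressed graph
#'
#' Two workflows over a [compress()]ed graph. `expand = FALSE` is the
#' paper-faithful fast path: a plain census of the retained graph `g_r`
#' (comparable across networks compressed the same way, but not equal to
#' the full census). `expand = TRUE` runs the multiplicity-aware
#' enumeration and [expand_census()], recovering the census of the original
#' graph exactly.
#'
#' @param cg a `compressed_graph` from [compress()].
#' @param k subgraph size.
#' @param expand logical; see above.
#' @return a `subgraph_census`.
#' @export
census_compressed <- function(cg, k, expand = TRUE) {
  if (!inherits(cg, "compressed_graph")) stop("expected a compressed_graph")
  if (!expand) return(subgraph_census(cg$g_r, k))
  expand_census(compressed_census(cg, k), k)
}
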