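#' Balanced-ternary Code objects
#'
#' A Code is the integer obtained by reading an incidence matrix row by row
#' as balanced-ternary digits (+1, 0, -1), most significant digit first:
#' `value = sum(d_i * 3^(N - i))` over the `N = n_rows * n_cols` flattened
#' entries. One canonical Code marks each isomorphism class of connected
#' digraphs (see [canonical_code()]). Values routinely exceed 64-bit range,
#' so they are carried as exact decimal strings alongside the digit vector;
#' two Codes are equal iff value, n_rows and n_cols all agree (a value alone
#' could in principle recur at a different shape).
#'
#' @param value decimal string (or exact numeric below 2^53).
#' @param n_rows,n_cols matrix shape the digits are read from.
#' @return an object of class `ternary_code` with fields `value` (string),
#'   `digits` (integer vector, most significant first), `n_rows`, `n_cols`.
#' @export
ternary_code <- function(value, n_rows, n_cols) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 0L)
  s <- .bt_as_value_string(value)
  digits <- .bt_string_to_digits(s, n_rows * n_cols)
  .new_code(digits, n_rows, n_cols, s)
}

.new_code <- function(digits, n_rows, n_cols, value = NULL) {
  structure(list(value = if (is.null(value)) .bt_digits_to_string(digits)
                         else value,
                 digits = as.integer(digits),
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols)),
            class = "ternary_code")
}

#' @export
print.ternary_code <- function(x, ...) {
  cat("ternary_code ", x$value, " (", x$n_rows, "x", x$n_cols, ")\n",
      sep = "")
  invisible(x)
}

#' @export
format.ternary_code <- function(x, ...) x$value

#' @export
as.character.ternary_code <- function(x, ...) x$value

#' @export
`==.ternary_code` <- function(e1, e2) {
  identical(e1$value, e2$value) && identical(e1$n_rows, e2$n_rows) &&
    identical(e1$n_cols, e2$n_cols)
}

# census/report key carrying shape alongside the value
.code_key <- function(code) {
  paste0(code$value, "@", code$n_rows, "x", code$n_cols)
}

#' Encode an incidence matrix as a balanced-ternary Code
#'
#' Flattens the matrix row-major into digits `d_1..d_N` (`d_1` most
#' significant) and evaluates `sum(d_i * 3^(N - i))` exactly. The worked
#' normalization example of the method, the 4x4 matrix of the directed
#' 4-cycle, encodes to 13698880.
#'
#' @param m integer matrix with entries in `{-1, 0, 1}` (an
#'   [incidence_matrix()] result or any such grid).
#' @return a [ternary_code()].
#' @examples
#' m <- rbind(c(1,0,0,-1), c(-1,1,0,0), c(0,-1,1,0), c(0,0,-1,1))
#' encode_symmetric_ternary(m)$value   # "13698880"
#' @export
encode_symmetric_ternary <- function(m) {
  m <- as.matrix(m)
  if (!all(m %in% c(-1L, 0L, 1L))) {
    stop("matrix entries must be -1, 0 or 1")
  }
  digits <- as.integer(t(m))  # row-major flatten
  .new_code(digits, nrow(m), ncol(m))
}

#' Decode a Code back into its matrix
#'
#' Exact left inverse of [encode_symmetric_ternary()]:
#' `decode_symmetric_ternary(encode_symmetric_ternary(m)) == m` for every
#' valid matrix. Used to render a canonical Code back as a topology for
#' reports.
#'
#' @param code a `ternary_code`, or a decimal value (string/numeric) with
#'   `n_rows`, `n_cols` supplied.
#' @param n_rows,n_cols shape, required when `code` is a bare value.
#' @return integer matrix with entries in `{-1, 0, 1}`.
#' @export
decode_symmetric_ternary <- function(code, n_rows = NULL, n_cols = NULL) {
  if (!inherits(code, "ternary_code")) {
    if (is.null(n_rows) || is.null(n_cols)) {
      stop("n_rows and n_cols are required when decoding a bare value")
    }
    code <- ternary_code(code, n_rows, n_cols)
  }
  matrix(code$digits, nrow = code$n_rows, ncol = code$n_cols, byrow = TRUE)
}

# permutation matrices, memoized per k (k! x k; k <= 8)
.perm_cache <- new.env(parent = emptyenv())

.permutations <- function(k) {
  key <- as.character(k)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  res <- if (k == 1L) {
    matrix(1L, 1L, 1L)
  } else {
    sub <- .permutations(k - 1L)
    do.call(rbind, lapply(seq_len(k), function(i) {
      rest <- seq_len(k)[-i]
      cbind(i, matrix(rest[sub], nrow = nrow(sub)))
    }))
  }
  storage.mode(res) <- "integer"
  .perm_cache[[key]] <- res
  res
}

# TRUE iff digit vector a > b lexicographically (equal length).
.lex_gt <- function(a, b) {
  d <- which(a != b)
  length(d) > 0L && a[d[1L]] > b[d[1L]]
}

# Canonical digit vector for a k x k logical adjacency matrix: maximum
# row-major balanced-ternary reading over all vertex orderings, with edge
# columns sorted ascending by (source position, target position).
.canonical_digits_adj <- function(adj) {
  k <- nrow(adj)
  ed <- which(adj, arr.ind = TRUE)
  m <- nrow(ed)
  if (m == 0L) stop("connected graphs with >= 2 vertices have edges")
  perms <- .permutations(k)
  cols <- seq_len(m)
  best <- NULL
  for (p in seq_len(nrow(perms))) {
    pos <- perms[p, ]
    i <- pos[ed[, 1L]]
    j <- pos[ed[, 2L]]
    o <- order(i, j)
    d <- integer(k * m)
    d[(i[o] - 1L) * m + cols] <- 1L
    d[(j[o] - 1L) * m + cols] <- -1L
    if (is.null(best) || .lex_gt(d, best)) best <- d
  }
  best
}

# cache: adjacency signature -> ternary_code
.code_cache <- new.env(parent = emptyenv())

.adjacency_signature <- function(adj) {
  rawToChar(as.raw(48L + as.integer(adj)))
}

.canonical_code_adj <- function(adj) {
  sig <- .adjacency_signature(adj)
  code <- .code_cache[[sig]]
  if (is.null(code)) {
    digits <- .canonical_digits_adj(adj)
    code <- .new_code(digits, nrow(adj), length(digits) %/% nrow(adj))
    .code_cache[[sig]] <- code
  }
  code
}

#' Canonical Code of a connected digraph
#'
#' The unique mark of the graph's isomorphism class: the maximum
#' [encode_symmetric_ternary()] value over all vertex orderings, where for
#' each ordering the edge columns are sorted ascending by (source position,
#' target position). Deterministic, invariant under vertex relabeling, and
#' distinct for non-isomorphic graphs (verified in the test suite against a
#' brute-force permutation oracle). Practical for motif sizes only: the
#' search is over k! orderings, capped at k = 8.
#'
#' @param g a weakly connected `digraph` with 2..8 vertices.
#' @return a [ternary_code()].
#' @examples
#' canonical_code(digraph(rbind(c("u", "v"))))$value   # "2"
#' @export
canonical_code <- function(g) {
  .check_digraph(g)
  n <- vcount(g)
  if (n < 2L || n > 8L) stop("canonical_code requires 2 to 8 vertices")
  if (!is_weakly_connected(g)) stop("canonical_code requires a connected graph")
  .canonical_code_adj(.adjacency_matrix(g))
}

#' Edge list of the canonical exemplar of a Code
#'
#' Decodes a canonical Code into the topology it marks, on synthetic vertex
#' labels `v1..vk`, for human-readable reports.
#'
#' @param code a `ternary_code` produced by [canonical_code()].
#' @return single string like `"v1->v2;v1->v3;v2->v3"`.
#' @export
code_exemplar <- function(code) {
  m <- decode_symmetric_ternary(code)
  src <- apply(m, 2L, function(col) which(col == 1L)[1L])
  dst <- apply(m, 2L, function(col) which(col == -1L)[1L])
  paste(paste0("v", src, "->v", dst), collapse = ";")
}

#' Brute-force digraph isomorphism (test oracle)
#'
#' Plain permutation search: TRUE iff some vertex bijection maps the edge
#' set of `g1` exactly onto that of `g2`, directions preserved. Written
#' independently of [canonical_code()] so the two can cross-validate; only
#' usable for graphs of at most 8 vertices.
#'
#' @param g1,g2 `digraph` objects with at most 8 vertices each.
#' @return logical scalar.
#' @export
are_isomorphic_bruteforce <- function(g1, g2) {
  .check_digraph(g1)
  .check_digraph(g2)
  n <- vcount(g1)
  if (n > 8L || vcount(g2) > 8L) stop("oracle limited to 8 vertices")
  if (n != vcount(g2) || ecount(g1) != ecount(g2)) return(FALSE)
  if (n == 0L) return(TRUE)
  # cheap necessary condition: matching degree-pair multisets
  d1 <- degree_pairs(g1)
  d2 <- degree_pairs(g2)
  if (!identical(sort(paste0(d1[, 1], ",", d1[, 2])),
                 sort(paste0(d2[, 1], ",", d2[, 2])))) {
    return(FALSE)
  }
  a1 <- .adjacency_matrix(g1)
  a2 <- .adjacency_matrix(g2)
  perms <- .permutations(n)
  for (p in seq_len(nrow(perms))) {
    f <- perms[p, ]  # g1 vertex i -> g2 vertex f[i]
    if (identical(a1, a2[f, f, drop = FALSE])) return(TRUE)
  }
  FALSE
}
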