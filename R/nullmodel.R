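#' Ensemble specification for the null model
#'
#' @param n_networks number of randomized networks (the classical motif
#'   criterion uses 1000).
#' @param attempts_per_edge Markov-chain swap trials per edge for each
#'   network; proposal rejections count, keeping run length deterministic.
#' @param seed integer; member i is randomized with `seed + i`.
#' @return a list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_networks = 1000L, attempts_per_edge = 10L, seed) {
  n_networks <- as.integer(n_networks)
  attempts_per_edge <- as.integer(attempts_per_edge)
  if (n_networks < 1L || attempts_per_edge < 1L) {
    stop("n_networks and attempts_per_edge must be >= 1")
  }
  if (missing(seed)) stop("seed is required")
  structure(list(n_networks = n_networks,
                 attempts_per_edge = attempts_per_edge,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Degree-preserving edge-swap randomization
#'
#' The standard null model: a Markov chain whose move picks two distinct
#' edges `a->b`, `c->d` uniformly and rewires them to `a->d`, `c->b` iff
#' that creates no self-loop and no duplicate edge. Every vertex keeps its
#' exact `(d_in, d_out)`; edge count and simplicity are conserved. Graphs
#' admitting no valid swap are returned unchanged.
#'
#' @param g a `digraph`
#' @param attempts number of swap trials (rejections included).
#' @param seed integer seed; the result is a pure function of `(g, attempts,
#'   seed)`.
#' @return a `digraph` with the same vertices and degree sequence.
#' @export
swap_randomize <- function(g, attempts, seed) {
  .check_digraph(g)
  m <- ecount(g)
  if (m < 2L) return(g)
  from <- g$from
  to <- g$to
  exists <- new.env(parent = emptyenv(), size = max(29L, 2L * m))
  for (i in seq_len(m)) exists[[paste0(from[i], ",", to[i])]] <- TRUE
  .with_seed(seed, {
    for (t in seq_len(attempts)) {
      e <- sample.int(m, 2L)
      a <- from[e[1L]]; b <- to[e[1L]]
      cc <- from[e[2L]]; d <- to[e[2L]]
      if (a == d || cc == b) next
      k1 <- paste0(a, ",", d)
      k2 <- paste0(cc, ",", b)
      if (!is.null(exists[[k1]]) || !is.null(exists[[k2]])) next
      rm(list = c(paste0(a, ",", b), paste0(cc, ",", d)), envir = exists)
      exists[[k1]] <- TRUE
      exists[[k2]] <- TRUE
      to[e[1L]] <- d
      to[e[2L]] <- b
    }
  })
  digraph(cbind(g$vertices[from], g$vertices[to]), vertices = g$vertices)
}

#' Generate a degree-preserving randomized ensemble
#'
#' `n_networks` independent randomizations of `g`; member i uses seed
#' `spec$seed + i` and `spec$attempts_per_edge * ecount(g)` swap trials.
#' Fully reproducible from the spec.
#'
#' @param g a `digraph`
#' @param spec an [ensemble_spec()].
#' @return list of `digraph` objects.
#' @export
generate_ensemble <- function(g, spec) {
  if (!inherits(spec, "ensemble_spec")) stop("expected an ensemble_spec")
  attempts <- spec$attempts_per_edge * ecount(g)
  lapply(seq_len(spec$n_networks), function(i) {
    swap_randomize(g, attempts, spec$seed + i)
  })
}
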