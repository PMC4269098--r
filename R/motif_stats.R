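#' Right-tail empirical frequency P
#'
#' Fraction of ensemble censuses whose count for a class reaches the real
#' count: `#\{i : rand_counts[i] >= n_real\} / length(rand_counts)`. Ties
#' count against significance; no pseudo-count correction, matching the
#' literal "P < 0.01 from 1000 randomized networks" reading.
#'
#' @param n_real count of the class in the input graph.
#' @param rand_counts numeric vector of ensemble counts (one per member).
#' @return probability in `[0, 1]`.
#' @export
empirical_p <- function(n_real, rand_counts) {
  if (length(rand_counts) == 0L) stop("empty ensemble")
  mean(rand_counts >= n_real)
}

#' Three-criterion motif decision for one subgraph class
#'
#' A class is called a motif iff all of:
#' (i) empirical frequency `P < 0.01`;
#' (ii) `n_real > 4` (strictly larger than four);
#' (iii) `n_real - mean(rand_counts) > 0.1 * mean(rand_counts)`.
#' The z-score is reported for ranking but plays no part in the decision;
#' it is NaN when the ensemble standard deviation is zero.
#'
#' @inheritParams empirical_p
#' @param code optional [ternary_code()] attached to the verdict.
#' @return object of class `motif_verdict`: `code`, `n_real`,
#'   `n_rand_mean`, `n_rand_sd`, `p_value`, `z_score`, `is_motif`.
#' @export
motif_decision <- function(n_real, rand_counts, code = NULL) {
  p <- empirical_p(n_real, rand_counts)
  mu <- mean(rand_counts)
  sdv <- stats::sd(rand_counts)
  if (length(rand_counts) == 1L) sdv <- 0
  z <- if (sdv == 0) NaN else (n_real - mu) / sdv
  structure(list(code = code, n_real = n_real, n_rand_mean = mu,
                 n_rand_sd = sdv, p_value = p, z_score = z,
                 is_motif = (p < 0.01) && (n_real > 4) &&
                   (n_real - mu > 0.1 * mu)),
            class = "motif_verdict")
}

#' @export
print.motif_verdict <- function(x, ...) {
  cat("motif_verdict", if (!is.null(x$code)) x$code$value else "",
      " n_real=", format(x$n_real),
      " n_rand=", format(round(x$n_rand_mean, 3)),
      " p=", format(x$p_value), " z=", format(round(x$z_score, 3)),
      if (x$is_motif) "  MOTIF" else "", "\n", sep = "")
  invisible(x)
}

#' Mine motifs: census, null ensemble, three-criterion verdicts
#'
#' End-to-end pipeline: census of the input graph at size `k`, censuses of
#' `spec$n_networks` degree-preserving randomizations processed with the
#' *same* compression mode as the input, and a [motif_decision()] per
#' class found in the input graph. Codes absent from an ensemble member
#' count as 0 there. Classes appearing only in the ensemble cannot satisfy
#' the abundance criterion and are not reported.
#'
#' Compression modes: `"off"` is the direct census; `"exact"` compresses
#' parity nodes and expands counts back (identical numbers to `"off"`,
#' smaller search); `"fast"` compares retained-graph censuses directly --
#' the workflow that compresses the random networks "in the same way" --
#' which is cheap but statistically delicate because real and random
#' networks need not compress alike.
#'
#' No multiple-testing correction is applied across classes; the three
#' criteria are applied per class, as is standard for this statistic.
#'
#' @param g a `digraph`
#' @param k subgraph size (3..8 typical; capped at 8).
#' @param spec an [ensemble_spec()].
#' @param compression `"off"`, `"exact"`, or `"fast"`.
#' @param sample_probs optional RAND-ESU depth probabilities (length `k`),
#'   applied to the real and every random census alike.
#' @return object of class `motif_report`: `table` (data.frame with one row
#'   per class: code, n_real, n_rand_mean, n_rand_sd, p_value, z_score,
#'   is_motif, exemplar), sorted by z-score descending (NaN last);
#'   `verdicts` (list of `motif_verdict`); `meta` (k, seed, n_networks,
#'   attempts_per_edge, compression, version).
#' @export
mine_motifs <- function(g, k, spec, compression = c("off", "exact", "fast"),
                        sample_probs = NULL) {
  .check_digraph(g)
  if (!inherits(spec, "ensemble_spec")) stop("expected an ensemble_spec")
  compression <- match.arg(compression)
  census_of <- function(graph, seed_offset) {
    if (compression == "off") {
      subgraph_census(graph, k, sample_probs = sample_probs,
                      seed = if (is.null(sample_probs)) NULL
                             else spec$seed + seed_offset)
    } else {
      if (!is.null(sample_probs)) {
        stop("sampled enumeration is only available with compression = 'off'")
      }
      census_compressed(compress(graph), k,
                        expand = identical(compression, "exact"))
    }
  }
  real <- census_of(g, 0L)
  keys <- names(real$counts)
  rand <- matrix(0, nrow = spec$n_networks, ncol = length(keys),
                 dimnames = list(NULL, keys))
  attempts <- spec$attempts_per_edge * ecount(g)
  for (i in seq_len(spec$n_networks)) {
    rg <- swap_randomize(g, attempts, spec$seed + i)
    ci <- census_of(rg, i)
    hit <- intersect(names(ci$counts), keys)
    rand[i, hit] <- ci$counts[hit]
  }
  verdicts <- lapply(keys, function(key) {
    motif_decision(real$counts[[key]], rand[, key], code = real$codes[[key]])
  })
  tab <- data.frame(
    code = vapply(verdicts, function(v) v$code$value, character(1)),
    n_real = vapply(verdicts, function(v) v$n_real, numeric(1)),
    n_rand_mean = vapply(verdicts, function(v) v$n_rand_mean, numeric(1)),
    n_rand_sd = vapply(verdicts, function(v) v$n_rand_sd, numeric(1)),
    p_value = vapply(verdicts, function(v) v$p_value, numeric(1)),
    z_score = vapply(verdicts, function(v) v$z_score, numeric(1)),
    is_motif = vapply(verdicts, function(v) v$is_motif, logical(1)),
    exemplar = vapply(keys, function(key) code_exemplar(real$codes[[key]]),
                      character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  o <- order(-tab$z_score, tab$code, na.last = TRUE)
  structure(list(table = tab[o, , drop = FALSE],
                 verdicts = verdicts[o],
                 meta = list(k = as.integer(k), seed = spec$seed,
                             n_networks = spec$n_networks,
                             attempts_per_edge = spec$attempts_per_edge,
                             compression = compression,
                             version = as.character(
                               utils::packageVersion("motifspace")))),
            class = "motif_report")
}

#' @export
print.motif_report <- function(x, ...) {
  cat("motif_report: k=", x$meta$k, ", ", nrow(x$table), " class(es), ",
      sum(x$table$is_motif), " motif(s); ensemble n=", x$meta$n_networks,
      ", seed=", x$meta$seed, ", compression=", x$meta$compression,
      "\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}
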