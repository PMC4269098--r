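---
title: "Motif mining with incidence-matrix Codes and parity-node compression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif mining with incidence-matrix Codes and parity-node compression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifspace)
```

## The problem

A *network motif* is a small connected subgraph topology that occurs in a
real directed network significantly more often than in random networks with
the same degree sequence. In transcription-regulation networks such
topologies (the feed-forward loop above all) are read as candidate
functional building blocks. Calling motifs requires three ingredients, each
of which dominates cost at a different scale: enumerating all connected
induced k-subgraphs, deciding which enumerated subgraphs are isomorphic,
and repeating both over a randomized ensemble.

`motifspace` implements a specific combination: isomorphism handled by an
integer *Code* derived from the vertex–edge incidence matrix, and the
search space shrunk beforehand by removing interchangeable (*parity*)
vertices.

## The model and its pieces

### Incidence matrices and Codes

A digraph on n vertices and m edges is stored as its incidence matrix
M(G): rows are vertices, columns are edges, +1 marks the source row of a
column's edge and −1 its target. Every column holds exactly one +1 and one
−1, so the matrix sums to zero and the count of +1 entries equals m. This
representation cannot express self-loops, which is why the package rejects
them outright rather than dropping them silently.

Reading M(G) row by row yields N = n·m digits in {−1, 0, +1}: a
balanced-ternary number, `value = sum(d_i * 3^(N-i))`. Two matrices of
equal shape are equal iff their values are equal, so the integer is a
faithful fingerprint of one *ordered* matrix.

To mark an isomorphism *class*, the matrix must first be canonically
ordered. The normalization rule used by the method's original source is not
recoverable from its text, and its printed per-class Code table is
therefore not reproducible; the package fixes its own rule once:

> canonical Code = the maximum encoding over all vertex orderings, with
> edge columns sorted ascending by (source position, target position).

This is well defined, isomorphism-invariant by construction (the maximum
over a set that depends only on the unlabeled graph), and cheap at motif
sizes — at most 8! orderings, and in practice canonicalization is memoized
on the induced adjacency pattern so each distinct pattern is canonicalized
once per session. The one printed value that *is* normalization-independent
— the encoding of the worked 4×4 example matrix, 13698880 — is an
acceptance target and reproduced exactly:

```{r}
g <- digraph(rbind(c("1","3"), c("3","2"), c("2","4"), c("4","1")))
encode_symmetric_ternary(incidence_matrix(g, c("1","3","2","4")))$value
```

Codes grow to hundreds of ternary digits (k = 8 allows up to 8×56 = 448),
far beyond 64-bit integers. No arbitrary-precision package is assumed:
values are carried as exact decimal strings backed by base-10^15 limb
arithmetic, and all comparisons during canonicalization happen on the
digit vectors themselves (for fixed length, balanced-ternary value order
is lexicographic order on digits). Codes serialize as decimal strings
everywhere; equality always includes the matrix shape.

The test suite realizes the uniqueness claim as a property: on all
weakly-connected 3-vertex digraphs (13 classes) and on 200 random connected
4-vertex digraphs, Code equality coincides pair-by-pair with a brute-force
permutation isomorphism oracle implemented independently of the Code path.

### Enumeration

The enumeration contract is the ESU one: every vertex set of size k whose
induced subgraph is weakly connected is yielded exactly once, by growing
from each anchor vertex using only exclusive neighbors with input order
greater than the anchor. Induced subgraphs and direction-ignoring
connectivity are the standard census conventions; the method's own terse
backtracking description is compatible with them and too underspecified to
pin anything stricter. Neighbor exploration follows ascending input order,
which makes runs deterministic across platforms.

The sampled variant explores each depth-d extension with probability
`sample_probs[d]` and weights every yielded set by
`1 / prod(sample_probs)`, giving unbiased weighted counts (tested against
the exact totals at 3 standard errors over 200 seeded runs).

`k` is capped at 8: beyond that both the k! canonicalization bound and the
Code length make the approach inappropriate.

### Parity nodes and space compression

Vertices with equal `(d_in, d_out)` are *parity nodes* by the degree
definition. Equal degrees alone, however, do not make two vertices
exchangeable — the correctness claim behind compression ("exchanging two
parity nodes does not affect the topology") holds exactly for *structural
twins*: identical out-neighbor and in-neighbor sets outside the class, and
uniform intra-class adjacency (no edges at all among members, *false
twins*, or all mutual edges, *true twins*). Swapping two such vertices is a
graph automorphism, which the suite asserts literally (`swap_labels` then
`graph_identical`). The package therefore defaults to structural mode and
provides degree mode for fidelity to the looser definition, documented and
flagged as count-unsafe.

Two useful facts make detection simple: if two vertices have identical
*open* neighborhoods, an intra-class edge would imply a self-loop, so open
equality already characterizes false twins; identical *closed*
neighborhoods force full mutual connection, characterizing true twins. A
vertex can qualify as a false twin of one set and a true twin of another;
such conflicts are resolved greedily and deterministically (false-twin
classes claim members first, in order of their minimum-input-order
representative). This forfeits maximality in rare mixed cases but never
validity, which is what count recovery needs.

Compression removes all members but the minimum-input-order representative
of each class, yielding the decomposition: retained graph `g_r`, removed
parity vertices `g_p`, and `g_cv`, the original edges incident to removed
vertices. The three parts partition the original exactly (tested).

### Exact count recovery

The multiplicity-aware census keeps `min(size, k)` members per class (the
"clone graph"), enumerates it exhaustively, and converts counts in two
steps:

* raw clone-graph counts are divided by `prod(choose(kept_c, r_c))` — the
  clones of a class are interchangeable, so each distinct multiset
  embedding (a pattern using `r_c` members of class c) was seen exactly
  that many times;
* each multiset embedding is then weighted by `prod(choose(size_c, r_c))`,
  the number of ways to realize it in the uncompressed graph.

Because every permutation of a structural class is an automorphism, any
`r_c`-subset of a class induces the same pattern, which is what makes both
steps exact — censuses recovered this way equal direct censuses class by
class on 50 synthetic graphs with planted twin classes at k ∈ {3, 4}
(acceptance criterion). The paper-faithful alternative — comparing
compressed censuses directly between the real network and its
randomizations, each compressed in the same way — is exposed as
`compression = "fast"`; it reproduces that workflow but real and random
networks need not compress identically, so the exact mode is the default
for motif calls.

### Null model and the motif call

The null ensemble is the standard degree-preserving Markov chain: a trial
picks two distinct edges a→b, c→d uniformly and rewires to a→d, c→b unless
that would create a self-loop or duplicate edge. Rejected proposals count
toward the attempt budget, keeping run length deterministic. The mixing
parameter `attempts_per_edge` defaults to 10 — the method states none, and
10 swaps per edge is common practice for edge-swap nulls; it is exposed as
a flag. Mutual-edge counts are *not* separately conserved (plain swap
null); some motif literature conserves them, which would shift verdicts
for mutual-edge-rich classes.

For each Code found in the input graph, with ensemble counts treating an
absent Code as 0:

* `P` = fraction of ensemble members whose count reaches the real count
  (ties count against significance; no pseudo-count, matching the literal
  "P < 0.01 from 1000 randomized networks");
* motif iff `P < 0.01` and `N_real > 4` (strictly) and
  `N_real − N_rand > 0.1 · N_rand`, with `N_rand` the ensemble mean;
* a z-score is reported for ranking only, NaN when the ensemble is
  degenerate.

No multiple-testing correction is applied across classes — the three
criteria are per-class, as in the original formulation; reports should be
read accordingly.

## What the synthetic generators emulate

`random_digraph(n, m, seed)` draws uniform simple digraphs with exactly m
edges; `plant_twins` adds classes of exact structural twins with a shared
random external neighborhood; `plant_motif` inserts vertex-disjoint
pattern copies on fresh vertices, with background edges confined to
non-planted vertices so the planted count lower bound is provable rather
than probabilistic. All generators are pure functions of their seed.

These fixtures state the world the tests certify: graphs of tens of
vertices, planted classes of sizes 2–5 of both twin kinds, 20 planted
feed-forward loops on a 25-vertex/35-edge sparse background against a
200-member ensemble for the end-to-end criterion. A green suite
establishes correctness of the census, compression, null model and
decision arithmetic on such inputs; it does not establish biological
realism (no duplication–divergence structure, no autoregulation — real
transcription networks contain self-loops that must be stripped upstream),
nor the published wall-clock speedups, which are hardware statements and
out of scope.

## Numerical and design choices

* Ordering ties everywhere are broken by input order ("mark number"):
  class representatives, enumeration order, greedy twin splits.
* Codes compare by digit vector during canonicalization — no big-integer
  division in the hot path; decimal strings are produced once per class.
* Census keys carry the matrix shape; values alone could collide across
  shapes.
* Empirical P with ≤ ties → against significance makes P = 0 attainable
  only when no member reaches the real count, the conservative reading.
* `ensemble_spec` seeds member i with `seed + i`; every stage is a pure
  function of the spec, so reports are byte-identical across reruns.
* Scaled-down test budgets: the type-I sanity property runs 100 replicate
  mines at 40–60 member ensembles rather than 200×1000 — the bound tested
  (≤ 5% of per-class P values below 0.01 under the null) is unchanged.

## Known limitations

* Self-loops are rejected, not modeled; real regulatory networks require
  removing autoregulation first.
* Degree-mode parity classes are count-unsafe by design (provided for
  definitional fidelity only).
* Canonicalization is k!-bounded; k > 8 is out of scope, as are
  non-induced frequency concepts and motif generalizations (anti-motifs,
  significance profiles).
* The published per-class Code table (beyond the worked 4×4 example) uses
  an unspecified normalization and is deliberately not a reproduction
  target; class *counts*, not Code numerals, are the comparable quantity.
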