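---
title: "Methods: exact linearization of weighted adjacencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact linearization of weighted adjacencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linchrom)
```

## Model and assumptions

The input is a *degree-2 binary matrix*: a set of rows, each naming an
unordered pair of marker columns (an *adjacency*) and carrying a positive
weight, together with a copy-number map `m` assigning each marker `c` a
maximum number of occurrences `m(c) >= 1` (default 1). Rows must be
pairwise distinct as column sets, and a row may not repeat a marker
(no self-adjacencies).

A subset of rows is *realizable* when there is a set of linear and/or
circular chromosomes — sequences of marker occurrences — such that

1. every chosen adjacency `{x, y}` appears as a consecutive pair
   (including the wrap-around pair of a circular chromosome) exactly
   once over all chromosomes,
2. every marker occurs at least once and at most `m(c)` times in total.

The task solved by `linearize()` is to pick a realizable subset of
maximum total weight. Identifying the matrix with a weighted graph
(markers = vertices, rows = edges), realizability of a row subset is
equivalent to the degree bound `deg(c) <= 2 m(c)` holding at every
marker: each occurrence of a marker has at most two neighbours, and
conversely any subgraph meeting the bound decomposes into the required
sequences. So the optimization is a maximum-weight degree-constrained
subgraph ("2m-matching") problem, solvable in polynomial time.

## The gadget reduction

`build_gadget()` turns the 2m-matching instance into an ordinary
maximum-weight matching instance:

* every marker `x` becomes `f(x)` *copy vertices* `x#1 … x#f(x)`, where
  `f(x) = 2 m(x)` by default;
* every row `e = {x, y}` with weight `w` becomes two *port vertices*
  `e@x`, `e@y`, joined to each other by an edge of weight `w`, and each
  port is joined to every copy vertex of its marker, also with weight
  `w`.

For any maximum-weight matching of the gadget, a row is *selected*
exactly when **both** of its ports are matched to copy vertices. The
construction preserves weights additively: writing `W` for the total
weight of all rows,

> maximum matching weight = `W` + weight of the selected row subset,

because an unselected row contributes its port–port edge (weight `w`)
while a selected row contributes two port–copy edges (weight `2w`).
`verify_weight_relation()` re-checks this identity on every run, and the
selected subset is a maximum-weight 2m-matching.

`linearize()` internally caps the number of copy vertices at
`min(2 m(x), deg(x))`; extra copies beyond the degree can never be
matched to distinct ports, so the feasible set is unchanged while large
copy numbers stay cheap.

## Exact arithmetic

The blossom solver (C++, primal-dual with dual variables maintained at
twice their value) performs only additions, subtractions and halvings of
edge weights. With integer inputs all duals stay dyadic rationals that
are exactly representable in doubles, so the computed optimum is exact.
`scale_weights()` therefore tries to scale all weights by a power of ten
(up to `1e6`) to integers; the synthetic generators emit rationals with
denominator `1e4`, so package-generated instances are always solved
exactly. If no scaling makes the weights integral, weights are passed
through unchanged and all comparisons fall back to a `1e-9` tolerance;
`RunStats$exact_arithmetic` records which regime applied.

## Chromosome decomposition

The selected subgraph is decomposed component by component:

* a component whose vertex degrees are all even carries an Eulerian
  circuit and is emitted as **exactly one circular chromosome**;
* a component with `2k > 0` odd-degree vertices is closed up by `k`
  virtual edges pairing the odd vertices (sorted lexicographically and
  paired in order — a deterministic, arbitrary choice among optima), and
  the Eulerian circuit of the closed graph is split at the virtual edges
  into `k` edge-disjoint open trails, the minimum possible number of
  linear chromosomes;
* isolated markers are emitted as length-1 linear chromosomes so every
  marker occurs at least once.

A marker of copy number `m(c)` may legitimately occur fewer than `m(c)`
times; the decomposition emits the minimum number of occurrences implied
by the trails (`(degree + trail endpoints at the marker) / 2`, at least
1), never padding occurrences up to the bound. Ties between equally
heavy optimal subsets are broken by the solver deterministically but not
according to any semantic preference.

```{r figure-eight}
# two cycles sharing a duplicated hub marker v
m8 <- adj_matrix(data.frame(
  cols = I(list(c("v","a"), c("a","b"), c("b","v"),
                c("v","c"), c("c","d"), c("d","v"))),
  weight = rep(1, 6)))
res <- linearize(m8, mult_map(c(v = 2L)))
res$genome
res$stats$occurrences[["v"]]
```

## Oracles

Because the solver is the component most worth distrusting, the package
ships independent exhaustive references, all restricted to toy sizes:

* `brute_force_matching()` — all matchings by edge branching (≤ 22
  edges);
* `brute_force_max_2m_matching()` — all `2^rows` row subsets (≤ 20
  rows);
* `solve_23ucr_brute()` / `brute_force_row_removal()` — for degree-2/3
  matrices viewed as 2,3-uniform hypergraphs, whether removing at most
  `k` hyperedges makes the rest coverable by a multiset of vertex pairs
  (each 3-edge contributing two overlapping pairs) with every vertex in
  at most 2 pairs; the two formulations are checked against each other;
* `check_genome_realizes()` — direct verification of conditions 1–2
  above against an explicit genome.

## Synthetic generator

`generate_planted()` draws a genome first and derives the instance from
it: markers (a chosen fraction with copy number 2) are arranged by
rejection sampling into the requested number of linear/circular
chromosomes such that no adjacency repeats and nothing is self-adjacent;
the genome's adjacency set becomes the planted rows with weights uniform
on the rationals `k/10^4` in the requested range. Decoy rows are then
added. In *strict* mode decoys connect only markers whose planted degree
already equals `2 m`, and every decoy weight lies strictly below every
planted weight; an exchange argument then shows the planted set is the
**unique** optimum (adding any set of decoys forces dropping at least as
many strictly heavier planted rows), which is what makes exact-recovery
testing sound. Requests that are combinatorially impossible (for
example, a lone circular chromosome over 4 markers with one duplicated
marker) are rejected with an error rather than silently adjusted.

The generator restores the session RNG state, and identical parameters
and seed give byte-identical instances.

## Problem sizes and performance

Sizes used in the package's own tests are package choices, not imposed
limits: oracle comparisons use ≤ 8 markers and ≤ 14 rows so exhaustive
enumeration stays trivial, and the scalability check runs 10,000 markers
with 15,000 rows, which completes in roughly two minutes on one CPU. The
blossom implementation is O(V·E) per augmentation stage with at most V
stages; the gadget at most doubles-plus-caps vertex counts, so overall
behavior is polynomial, comfortably so at the tested sizes.

## Limitations

* Only degree-2 matrices are linearized; degree-3 rows (intervals of
  three markers) are accepted by the oracles and file readers but not by
  the solver, where the underlying problem is no longer polynomial.
* Weights that cannot be scaled to integers by `1e6` are handled with a
  floating-point tolerance rather than exactly.
* The reported genome is one optimal realization; when several optima
  exist, no biological preference (e.g. fewer circular chromosomes) is
  applied.
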