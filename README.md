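# linchrom

Linearize a weighted set of candidate gene adjacencies into a
multichromosomal genome.

## The problem

Ancestral genome reconstruction pipelines produce a set of *candidate
adjacencies*: unordered pairs of markers (genes or gene extremities),
each weighted by how strongly the data support that the two markers were
neighbours in the ancestor. The candidate set is usually inconsistent —
no single genome can contain all of the adjacencies — so a maximum-weight
consistent subset has to be chosen and assembled into chromosomes.

`linchrom` solves this exactly for the classic model:

* the input is a weighted adjacency set (a degree-2 binary matrix: each
  row names two marker columns and carries a positive weight), plus an
  optional per-marker maximum copy number `m(c)` (default 1);
* a subset of adjacencies is *consistent* when it can be realized by a
  set of linear and/or circular chromosomes in which every marker `c`
  occurs between 1 and `m(c)` times and every chosen adjacency appears
  as a consecutive pair exactly once;
* for degree-2 input this is equivalent to finding a maximum-weight
  spanning subgraph in which every marker `c` has degree at most
  `2 m(c)` — a degree-constrained subgraph problem.

The solver reduces that problem to ordinary maximum-weight matching via a
vertex-splitting gadget (each marker becomes up to `2 m(c)` copy
vertices, each adjacency two port vertices), solves the matching with a
primal-dual blossom implementation in C++, and decomposes the selected
subgraph into chromosomes by Eulerian traversal: a component whose
degrees are all even becomes one circular chromosome; a component with
`2k` odd-degree vertices becomes `k` linear chromosomes; markers left
without any adjacency become single-marker linear chromosomes.

Rational weights (up to six decimal digits) are scaled to integers before
matching, so the optimum is computed in exact arithmetic.

## Quick start

```r
library(linchrom)

# three adjacencies around a hub marker b, with weights 5, 4, 3
m <- adj_matrix(data.frame(
  cols = I(list(c("b", "x"), c("b", "y"), c("b", "z"))),
  weight = c(5, 4, 3)))

# with every copy number 1, b can keep at most two neighbours
res <- linearize(m)
res$stats$optimum        # 9  (weights 5 + 4)
res$genome               # one linear chromosome x b y, plus z alone

# allowing two copies of b makes all three adjacencies consistent
res2 <- linearize(m, mult_map(c(b = 2L)))
res2$stats$optimum       # 12
```

Every result is verified internally: the genome is re-checked against the
selected rows (`check_genome_realizes`), and the matching-weight identity
`matching weight = total row weight + selected weight` is re-validated.
For small instances an independent exhaustive solver
(`brute_force_max_2m_matching`) is available as an oracle.

## File formats and command line

* adjacency TSV: `marker_a<TAB>marker_b<TAB>weight`, `#` comments;
* copy-number TSV: `marker<TAB>max_copies`, unlisted markers default 1;
* genome text: one chromosome per line, `C a b c` (circular, written in
  canonical rotation) or `L a b` (linear).

A command-line wrapper is installed with the package (find it with
`system.file("exec", "linchrom", package = "linchrom")`):

```sh
linchrom run --adjacencies adj.tsv --multiplicities mult.tsv \
  --out-genome genome.txt --stats-json stats.json
linchrom check --adjacencies adj.tsv --genome genome.txt
linchrom oracle --mode 2m --adjacencies adj.tsv
linchrom simulate --out-dir sim/ --seed 7 --n-markers 20 \
  --noise-edge-count 10
```

Exit codes: 0 success, 2 validation error, 3 internal invariant failure.

## Synthetic benchmarks

`generate_planted()` builds instances with a known optimal answer: it
draws a random genome, uses its adjacencies as the planted rows, and
appends strictly lighter decoy rows that each conflict with the planted
set, so the planted rows are the provably unique optimum. `linearize`
recovers them exactly; see the test suite and the methods vignette.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "linchrom",
                               load_package = "installed")'
```

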