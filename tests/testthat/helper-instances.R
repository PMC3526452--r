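# shared instance builders for the test suite

# adjacency matrix from "a-b" pair strings and matching weights
make_matrix <- function(pairs, weights = rep(1, length(pairs)),
                        markers = character()) {
  cols <- lapply(strsplit(pairs, "-", fixed = TRUE), identity)
  adj_matrix(data.frame(row_id = sprintf("e%02d", seq_along(cols)),
                        cols = I(cols), weight = weights),
             markers = markers)
}

k4_matrix <- function() {
  make_matrix(c("a-b", "a-c", "a-d", "b-c", "b-d", "c-d"))
}

star_matrix <- function() {
  make_matrix(c("b-x", "b-y", "b-z"), weights = c(5, 4, 3))
}

figure_eight_matrix <- function() {
  make_matrix(c("v-a", "a-b", "b-v", "v-c", "c-d", "d-v"))
}

# small random degree-2 instance for oracle comparisons
random_small_instance <- function(seed) {
  with_rng_seed(seed, {
    n <- sample(2:8, 1)
    ne <- sample(0:min(14, choose(n, 2)), 1)
    mm <- sample(1:2, 1)
    list(n = n, ne = ne, mm = mm)
  }) -> dims
  generate_random_graph(dims$n, dims$ne, max_mult = dims$mm, seed = seed)
}

# a fresh temporary file path (cleaned up with the session tempdir)
tmpfile <- function() tempfile(fileext = ".txt")

# igraph view of a selected row subset (vertex set = all markers)
selected_subgraph_for_test <- function(selected) {
  idx <- match(selected$row_ids, selected$matrix$rows$row_id)
  sub <- selected$matrix
  sub$rows <- sub$rows[idx, , drop = FALSE]
  matrix_to_graph(sub)
}
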