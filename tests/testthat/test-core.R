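test_that("adj_matrix collects markers and assigns row ids", {
  m <- make_matrix(c("a-b", "b-c"), weights = c(1.5, 2))
  expect_equal(m$markers, c("a", "b", "c"))
  expect_equal(nrow(m$rows), 2L)
  expect_equal(adj_degree(m), 2L)

  # extra declared markers survive as isolated columns
  m2 <- make_matrix("a-b", markers = c("z"))
  expect_true("z" %in% m2$markers)

  # empty matrix
  e <- adj_matrix(markers = c("a", "b"))
  expect_equal(nrow(e$rows), 0L)
  expect_equal(e$markers, c("a", "b"))
})

test_that("mult_map defaults to 1 and multiplicity() looks up values", {
  mu <- mult_map(c(b = 2L))
  expect_equal(unname(multiplicity(mu, c("a", "b"))), c(1L, 2L))
  expect_equal(unname(multiplicity(mult_map(), "x")), 1L)
})

test_that("validate_instance flags malformed instances", {
  good <- make_matrix(c("a-b", "b-c"))
  expect_length(validate_instance(good), 0L)

  self_adj <- adj_matrix(data.frame(row_id = "r1",
                                    cols = I(list(c("a", "a"))),
                                    weight = 1))
  expect_true(any(grepl("self", validate_instance(self_adj))))

  dup <- adj_matrix(data.frame(row_id = c("r1", "r2"),
                               cols = I(list(c("a", "b"), c("b", "a"))),
                               weight = c(1, 2)))
  expect_true(any(grepl("duplicate", validate_instance(dup))))

  neg <- adj_matrix(data.frame(row_id = "r1",
                               cols = I(list(c("a", "b"))),
                               weight = -1))
  expect_true(any(grepl("positive", validate_instance(neg))))

  badm <- make_matrix("a-b")
  expect_true(any(grepl("multiplicity",
                        validate_instance(badm, mult_map(c(a = 0L))))))
})

test_that("matrix_to_graph and graph_to_matrix round-trip", {
  m <- make_matrix(c("a-b", "b-c", "c-d"), weights = c(1, 2, 3),
                   markers = "iso")
  g <- matrix_to_graph(m)
  expect_equal(igraph::vcount(g), 5L)  # a b c d iso
  expect_equal(igraph::ecount(g), 3L)
  m2 <- graph_to_matrix(g)
  expect_setequal(m2$markers, m$markers)
  expect_equal(sum(m2$rows$weight), sum(m$rows$weight))
})

test_that("genome occurrences count markers across chromosomes", {
  g <- genome(list(list(kind = "circular", seq = c("v", "a", "b", "v",
                                                   "c", "d")),
                   list(kind = "linear", seq = "x")))
  occ <- genome_occurrences(g)
  expect_equal(unname(occ[["v"]]), 2L)
  expect_equal(unname(occ[["x"]]), 1L)
})

test_that("selected_rows computes the subset weight", {
  m <- make_matrix(c("a-b", "b-c", "c-d"), weights = c(1, 2, 4))
  s <- selected_rows(m, c("e01", "e03"))
  expect_equal(s$weight, 5)
  deg <- selected_degrees(s)
  expect_equal(unname(deg[["b"]]), 1L)
  expect_equal(unname(deg[["c"]]), 1L)
  expect_error(selected_rows(m, "nope"))
})
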