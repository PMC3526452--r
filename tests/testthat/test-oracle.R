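test_that("is_2m_matching enforces per-marker degree bounds", {
  m <- star_matrix()
  all3 <- selected_rows(m, m$rows$row_id)
  expect_false(is_2m_matching(all3, mult_map()))           # deg(b)=3 > 2
  expect_true(is_2m_matching(all3, mult_map(c(b = 2L))))   # deg(b)=3 <= 4
  two <- selected_rows(m, m$rows$row_id[1:2])
  expect_true(is_2m_matching(two, mult_map()))
})

test_that("C1P and Ci1P checks distinguish paths from cycles", {
  path <- make_matrix(c("a-b", "b-c"))
  sel <- selected_rows(path, path$rows$row_id)
  expect_true(is_c1p_degree2(sel))
  expect_true(is_ci1p_degree2(sel))

  tri <- make_matrix(c("a-b", "b-c", "a-c"))
  sel <- selected_rows(tri, tri$rows$row_id)
  expect_false(is_c1p_degree2(sel))     # a cycle is not a path collection
  expect_true(is_ci1p_degree2(sel))     # but it is a single spanning cycle

  # cycle plus a separate marker: not spanning, so not Ci1P
  tri2 <- make_matrix(c("a-b", "b-c", "a-c"), markers = "z")
  sel2 <- selected_rows(tri2, tri2$rows$row_id)
  expect_false(is_ci1p_degree2(sel2))
})

test_that("check_genome_realizes accepts exactly the right genomes", {
  m <- make_matrix(c("a-b", "b-c", "a-c"))
  sel <- selected_rows(m, m$rows$row_id)
  good <- genome(list(list(kind = "circular", seq = c("a", "b", "c"))))
  expect_true(check_genome_realizes(good, sel, mult_map()))

  # linear a b c misses the wrap pair {a,c}
  bad <- genome(list(list(kind = "linear", seq = c("a", "b", "c"))))
  expect_false(check_genome_realizes(bad, sel, mult_map()))

  # occurrence above m(c) is rejected
  over <- genome(list(list(kind = "linear", seq = c("a", "b", "c", "b",
                                                    "a", "c"))))
  expect_false(check_genome_realizes(over, sel, mult_map()))
})

test_that("brute_force_max_2m_matching solves tabulated examples", {
  expect_equal(brute_force_max_2m_matching(k4_matrix())$weight, 4)
  expect_equal(brute_force_max_2m_matching(star_matrix())$weight, 9)
  expect_equal(brute_force_max_2m_matching(star_matrix(),
                                           mult_map(c(b = 2L)))$weight, 12)
  empty <- adj_matrix(markers = c("a", "b"))
  expect_equal(brute_force_max_2m_matching(empty)$weight, 0)
})

test_that("23UCR brute force solves tabulated hypergraphs", {
  # a single 3-edge is coverable with no removals
  h1 <- hypergraph23(edges = list(c("a", "b", "c")))
  expect_true(solve_23ucr_brute(h1, 0)$feasible)

  # three 3-edges sharing the pair {a,b}: infeasible at k=0, feasible k=1
  h3 <- hypergraph23(edges = list(c("a", "b", "c"), c("a", "b", "d"),
                                  c("a", "b", "e")))
  expect_false(solve_23ucr_brute(h3, 0)$feasible)
  expect_true(solve_23ucr_brute(h3, 1)$feasible)

  # K4 as 2-edges: degree 3 everywhere; k=1 insufficient, k=2 enough
  k4 <- hypergraph23(edges = combn(letters[1:4], 2, simplify = FALSE))
  expect_false(solve_23ucr_brute(k4, 1)$feasible)
  expect_true(solve_23ucr_brute(k4, 2)$feasible)

  # witness structure: removed + covering reported when feasible
  sol <- solve_23ucr_brute(h3, 1)
  expect_length(sol$witness$removed, 1L)
})

test_that("hypergraph and matrix views are interconvertible", {
  m <- adj_matrix(data.frame(row_id = c("r1", "r2"),
                             cols = I(list(c("a", "b"), c("a", "b", "c"))),
                             weight = c(1, 1)))
  h <- matrix_to_hypergraph(m)
  expect_length(h$e2, 1L)
  expect_length(h$e3, 1L)
  m2 <- hypergraph_to_matrix(h)
  expect_equal(nrow(m2$rows), 2L)
  expect_setequal(m2$markers, m$markers)
})

test_that("row removal and hypergraph covering agree on small cases", {
  m3 <- adj_matrix(data.frame(row_id = c("r1", "r2", "r3"),
                              cols = I(list(c("a", "b", "c"),
                                            c("a", "b", "d"),
                                            c("a", "b", "e"))),
                              weight = c(1, 1, 1)))
  expect_false(brute_force_row_removal(m3, 0))
  expect_true(brute_force_row_removal(m3, 1))
})
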