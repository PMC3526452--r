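test_that("build_gadget produces the documented vertex and edge counts", {
  # triangle, m == 1: 2 copy vertices per marker + 2 ports per edge
  m <- make_matrix(c("a-b", "b-c", "a-c"))
  g <- matrix_to_graph(m)
  gad <- build_gadget(g, mult_map())
  expect_equal(length(gad$vertices), 12L)  # 6 copies + 6 ports
  expect_equal(nrow(gad$edges), 15L)       # 3 port-port + 12 port-copy
  # every gadget edge carries its row's weight
  expect_true(all(gad$edges$w == 1))
})

test_that("gadget matching weight equals W plus selected weight", {
  for (seed in 1:25) {
    inst <- generate_random_graph(6, 9, max_mult = 2, seed = seed + 900)
    g <- matrix_to_graph(inst$matrix)
    gad <- build_gadget(g, inst$mult)
    mm <- solve_max_weight_matching(gad)
    sel <- recover_f_matching(mm, gad, inst$matrix)
    expect_true(verify_weight_relation(mm, sel, inst$matrix))
    W <- sum(inst$matrix$rows$weight)
    expect_equal(mm$weight, W + sel$weight, tolerance = 1e-9)
  }
})

test_that("recovered row set is always a 2m-matching", {
  for (seed in 1:25) {
    inst <- generate_random_graph(7, 12, max_mult = 2, seed = seed + 300)
    res <- linearize(inst$matrix, inst$mult)
    expect_true(is_2m_matching(res$selected, inst$mult))
  }
})

test_that("decompose_to_chromosomes splits by component parity", {
  # triangle -> one circular chromosome
  m <- make_matrix(c("a-b", "b-c", "a-c"))
  sel <- selected_rows(m, m$rows$row_id)
  gen <- decompose_to_chromosomes(sel, mult_map())
  expect_equal(length(gen$chromosomes), 1L)
  expect_equal(gen$chromosomes[[1]]$kind, "circular")

  # path -> one linear chromosome
  m <- make_matrix(c("a-b", "b-c"))
  gen <- decompose_to_chromosomes(selected_rows(m, m$rows$row_id),
                                  mult_map())
  expect_equal(length(gen$chromosomes), 1L)
  expect_equal(gen$chromosomes[[1]]$kind, "linear")
  expect_equal(length(gen$chromosomes[[1]]$seq), 3L)

  # component with 6 odd-degree vertices (a,c,e,f and the two hubs b,d
  # at degree 3) -> 3 linear chromosomes
  m <- make_matrix(c("a-b", "b-c", "b-d", "d-e", "d-f"))
  gen <- decompose_to_chromosomes(selected_rows(m, m$rows$row_id),
                                  mult_map(c(b = 2L, d = 2L)))
  kinds <- vapply(gen$chromosomes, `[[`, "", "kind")
  expect_equal(sum(kinds == "linear"), 3L)
})

test_that("isolated markers become length-1 linear chromosomes", {
  m <- make_matrix("a-b", markers = c("lonely", "alone"))
  res <- linearize(m)
  occ <- res$stats$occurrences
  expect_equal(unname(occ[["lonely"]]), 1L)
  lens <- vapply(res$genome$chromosomes, function(ch) length(ch$seq), 0L)
  expect_equal(sum(lens == 1L), 2L)
})

test_that("linearize reports coherent run statistics", {
  inst <- generate_random_graph(8, 12, max_mult = 2, seed = 77)
  res <- linearize(inst$matrix, inst$mult)
  st <- res$stats
  expect_equal(st$rows_kept + st$rows_discarded, st$rows_total)
  expect_equal(st$rows_total, nrow(inst$matrix$rows))
  expect_lte(st$optimum, st$W + 1e-12)
  expect_equal(st$optimum, res$selected$weight, tolerance = 1e-12)
  expect_true(st$exact_arithmetic)
  ngen <- sum(vapply(res$genome$chromosomes, function(ch)
    ch$kind %in% c("linear", "circular"), TRUE))
  expect_equal(ngen, st$n_linear + st$n_circular)
})

test_that("linearize rejects degree-3 rows", {
  m3 <- adj_matrix(data.frame(row_id = "r1",
                              cols = I(list(c("a", "b", "c"))),
                              weight = 1))
  expect_error(linearize(m3), "degree")
})
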