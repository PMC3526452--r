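test_that("generator is deterministic given parameters and seed", {
  p <- synth_params(n_markers = 8, n_chromosomes = 2,
                    circular_fraction = 1, duplicated_fraction = 0.25,
                    noise_edge_count = 4, seed = 123)
  a <- generate_planted(p)
  b <- generate_planted(p)
  expect_identical(a$matrix$rows, b$matrix$rows)
  expect_identical(a$genome, b$genome)
  expect_identical(a$truth$planted_row_ids, b$truth$planted_row_ids)
})

test_that("planted genome realizes the planted rows", {
  for (seed in 1:20) {
    p <- synth_params(n_markers = 7, n_chromosomes = 2,
                      circular_fraction = 0.5,
                      duplicated_fraction = 0.3,
                      noise_edge_count = 3, seed = seed)
    inst <- suppressMessages(generate_planted(p))
    sel <- selected_rows(inst$matrix, inst$truth$planted_row_ids)
    expect_true(is_2m_matching(sel, inst$mult))
    expect_true(check_genome_realizes(inst$genome, sel, inst$mult))
    expect_equal(sel$weight, inst$truth$planted_weight)
    expect_length(validate_instance(inst$matrix, inst$mult), 0L)
  }
})

test_that("strict mode keeps every decoy lighter than every planted row", {
  p <- synth_params(n_markers = 8, circular_fraction = 1,
                    noise_edge_count = 5, seed = 42)
  inst <- suppressMessages(generate_planted(p))
  rows <- inst$matrix$rows
  planted <- rows$weight[rows$row_id %in% inst$truth$planted_row_ids]
  decoy <- rows$weight[!rows$row_id %in% inst$truth$planted_row_ids]
  if (length(decoy) > 0) {
    expect_lt(max(decoy), min(planted))
  }
  expect_error(synth_params(true_weight_range = c(1, 2),
                            noise_weight_range = c(0.5, 1.5),
                            strict = TRUE),
               "strict")
})

test_that("parameter validation rejects impossible requests", {
  expect_error(synth_params(n_markers = 0))
  expect_error(synth_params(circular_fraction = 2))
  p <- synth_params(n_markers = 2, n_chromosomes = 3, seed = 1)
  expect_error(generate_planted(p), "impossible")
})

test_that("generate_random_graph honours its size arguments", {
  inst <- generate_random_graph(6, 8, max_mult = 2, seed = 5)
  expect_equal(length(inst$matrix$markers), 6L)
  expect_equal(nrow(inst$matrix$rows), 8L)
  expect_true(all(unlist(inst$mult$values) %in% 1:2))
  expect_error(generate_random_graph(3, 10), "pairs")
})

test_that("rng state of the session is not disturbed", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_planted(synth_params(seed = 7)))
  expect_identical(.Random.seed, before)
})
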