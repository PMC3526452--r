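test_that("max_weight_matching matches hand-solved small graphs", {
  # path 1-2-3: pick the heavier edge
  e <- data.frame(i = c(1L, 2L), j = c(2L, 3L), w = c(2, 5))
  m <- max_weight_matching(e, 3L)
  expect_equal(matching_weight(m, e), 5)
  expect_true(is.na(m[1]))
  expect_equal(m[2], 3L)

  # triangle with one heavy edge
  e <- data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L), w = c(1, 1, 10))
  m <- max_weight_matching(e, 3L)
  expect_equal(matching_weight(m, e), 10)

  # even cycle: alternating edges
  e <- data.frame(i = 1:4, j = c(2L, 3L, 4L, 1L), w = c(3, 1, 3, 1))
  m <- max_weight_matching(e, 4L)
  expect_equal(matching_weight(m, e), 6)
})

test_that("max_weight_matching never picks a negative-value matching", {
  e <- data.frame(i = 1L, j = 2L, w = 0.5)
  m <- max_weight_matching(e, 2L)
  expect_equal(matching_weight(m, e), 0.5)
  expect_error(max_weight_matching(data.frame(i = 1L, j = 2L, w = -1), 2L),
               "positive")
})

test_that("blossom solver agrees with brute force on random graphs", {
  mismatches <- 0L
  for (seed in 1:120) {
    inst <- with_rng_seed(seed, {
      n <- sample(2:7, 1)
      maxe <- choose(n, 2)
      ne <- sample(1:maxe, 1)
      idx <- sample(maxe, ne)
      pairs <- t(combn(n, 2))[idx, , drop = FALSE]
      data.frame(i = pairs[, 1], j = pairs[, 2],
                 w = sample(1:50, ne, replace = TRUE) / 7)
    })
    m <- max_weight_matching(inst, max(inst$j))
    bf <- brute_force_matching(inst, max(inst$j))
    if (abs(matching_weight(m, inst) - bf$weight) > 1e-9) {
      mismatches <- mismatches + 1L
    }
  }
  expect_identical(mismatches, 0L)
})

test_that("solver handles odd cycles (blossoms) exactly", {
  # 5-cycle with unit weights: max matching has 2 edges
  e <- data.frame(i = 1:5, j = c(2:5, 1L), w = rep(1, 5))
  m <- max_weight_matching(e, 5L)
  expect_equal(matching_weight(m, e), 2)

  # two triangles joined by a bridge: the bridge edge is heavy
  e <- data.frame(i = c(1L, 2L, 1L, 4L, 5L, 4L, 3L),
                  j = c(2L, 3L, 3L, 5L, 6L, 6L, 4L),
                  w = c(1, 1, 1, 1, 1, 1, 10))
  m <- max_weight_matching(e, 6L)
  expect_equal(matching_weight(m, e), 12)
})

test_that("weight scaling detects rational weights exactly", {
  s <- scale_weights(c(0.1, 0.25, 1.75))
  expect_true(s$exact)
  expect_equal(s$scaled, c(10, 25, 175) * s$factor / 100)
  s2 <- scale_weights(pi)
  expect_false(s2$exact)
})
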