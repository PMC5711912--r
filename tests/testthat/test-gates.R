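# Gate evaluation, decoding, and the feedback gate's buffered table update.

test_that("deterministic gates evaluate their logic table", {
  ident <- deterministic_gate(c(0, 1), c(6, 7), 0:3)
  expect_equal(eval_deterministic(ident, 2L), 2L) # 0b10 -> 0b10
  nand <- deterministic_gate(c(0, 1), 6, c(1L, 1L, 1L, 0L))
  expect_equal(eval_deterministic(nand, 3L), 0L)
  expect_equal(eval_deterministic(nand, 0L), 1L)
  expect_error(eval_deterministic(nand, 4L), "out of range")
  expect_error(eval_deterministic(nand, -1L), "out of range")
})

test_that("a fixed payload decodes to a hand-decodable deterministic table", {
  # header: n_in byte 1 -> 2 inputs, n_out byte 0 -> 1 output;
  # addresses 3,5 (inputs), 2 -> node 6 (output); table bytes 9,4,7,2 mod 2
  payload <- c(1L, 0L, 3L, 5L, 0L, 0L, 2L, 0L, 0L, 0L, 9L, 4L, 7L, 2L,
               rep(0L, 263))
  span <- list(gate_kind = "deterministic", start = 1L, payload = payload)
  g <- decode_gate(span)
  expect_equal(g$input_nodes, c(3L, 5L))
  expect_equal(g$output_nodes, 6L)
  expect_equal(vapply(0:3, function(i) eval_deterministic(g, i), 0L),
               c(9, 4, 7, 2) %% 2)
})

test_that("probabilistic sampling follows the table distribution", {
  set.seed(21)
  # degenerate row: output forced
  g1 <- probabilistic_gate(c(0, 1), c(6, 7),
                           matrix(c(1, 0, 0, 0), 4, 4, byrow = TRUE))
  expect_true(all(eval_probabilistic(g1, 0L, n = 50) == 0L))
  # uniform row: frequencies within 3 standard errors of 1/4
  g2 <- probabilistic_gate(0, c(6, 7), matrix(0.25, 2, 4))
  draws <- eval_probabilistic(g2, 1L, n = 100000)
  freq <- tabulate(draws + 1L, 4) / length(draws)
  se <- sqrt(0.25 * 0.75 / length(draws))
  expect_true(all(abs(freq - 0.25) < 3 * se))
  expect_error(eval_probabilistic(g2, 2L), "out of range")
})

test_that("the feedback gate buffers its most recent decisions in order", {
  set.seed(22)
  g <- feedback_gate(0, c(6, 7), matrix(0.25, 2, 4), pos_node = 8,
                     neg_node = 9, depth = 2, delta_pos = c(0.3, 0.1))
  o1 <- eval_probabilistic(g, 0L)
  o2 <- eval_probabilistic(g, 1L)
  o3 <- eval_probabilistic(g, 0L)
  expect_equal(nrow(g$history), 2)
  expect_equal(unname(g$history[1, ]), c(0L, o3)) # most recent first
  expect_equal(unname(g$history[2, ]), c(1L, o2))
})

test_that("feedback shifts the credited entry and renormalizes the row", {
  g <- feedback_gate(c(0, 1), c(6, 7), matrix(0.25, 4, 4), pos_node = 8,
                     neg_node = 9, depth = 1, delta_pos = 0.5)
  g$history <- matrix(c(0L, 0L), 1, dimnames = list(NULL, c("i", "o")))
  apply_feedback(g, "positive", amounts = 0.2)
  # hand computation: target 0.25 + 0.2 = 0.45; others scaled by (1-0.45)/0.75
  expect_equal(g$table[1, ], c(0.45, 0.55 / 3, 0.55 / 3, 0.55 / 3),
               tolerance = 1e-12)
  expect_equal(sum(g$table[1, ]), 1, tolerance = 1e-12)
  # other rows untouched
  expect_equal(g$table[2:4, ], matrix(0.25, 3, 4))
  # negative feedback decreases the credited entry
  g2 <- feedback_gate(c(0, 1), c(6, 7), matrix(0.25, 4, 4), pos_node = 8,
                      neg_node = 9, depth = 1, delta_neg = 0.5)
  g2$history <- matrix(c(0L, 0L), 1)
  apply_feedback(g2, "negative", amounts = 0.1)
  expect_equal(g2$table[1, 1], 0.15, tolerance = 1e-12)
  expect_equal(sum(g2$table[1, ]), 1, tolerance = 1e-12)
})

test_that("an empty decision buffer makes feedback a no-op", {
  g <- feedback_gate(0, 6, matrix(0.5, 2, 2), pos_node = 8, neg_node = 9)
  P0 <- g$table
  apply_feedback(g, "positive")
  apply_feedback(g, "negative")
  expect_identical(g$table, P0)
})

test_that("probabilities stay inside [0.01, 0.99] under relentless feedback", {
  set.seed(23)
  g <- feedback_gate(c(0, 1), c(4, 5), matrix(0.25, 4, 4), pos_node = 0,
                     neg_node = 1, depth = 1, delta_pos = 0.5,
                     delta_neg = 0.5)
  g$history <- matrix(c(1L, 2L), 1)
  for (k in 1:10000) apply_feedback(g, "positive")
  expect_lte(max(g$table), 0.99)
  expect_gte(min(g$table), 0.01)
  expect_equal(rowSums(g$table), rep(1, 4), tolerance = 1e-9)
  for (k in 1:10000) apply_feedback(g, "negative")
  expect_gte(min(g$table), 0.01)
  expect_equal(rowSums(g$table), rep(1, 4), tolerance = 1e-9)
})

test_that("row-stochasticity is preserved by the feedback update", {
  set.seed(24)
  # the row update itself, over 10^4 random rows, targets and magnitudes
  worst <- 0
  low <- 1
  high <- 0
  for (case in 1:10000) {
    K <- sample(2:16, 1)
    row <- runif(K)
    row <- row / sum(row)
    o <- sample.int(K, 1)
    u <- runif(1, 0, 1)
    sgn <- sample(c(-1, 1), 1)
    res <- markovbrain:::.apply_one_r(row, o, u, sgn)
    worst <- max(worst, abs(sum(res) - 1))
    low <- min(low, res)
    high <- max(high, res[o])
  }
  expect_lt(worst, 1e-9)
  expect_gte(low, 0.01 - 1e-12)
  expect_lte(high, 0.99 + 1e-12)
  # and through whole gates with sampled decision buffers
  for (case in 1:200) {
    g <- random_fb_gate()
    for (e in 1:5) {
      eval_probabilistic(g, sample.int(nrow(g$table), 1) - 1L)
      apply_feedback(g, sample(c("positive", "negative"), 1))
    }
    expect_true(all(abs(rowSums(g$table) - 1) < 1e-9))
    expect_lte(max(g$table), 0.99 + 1e-12)
  }
})

test_that("zero-magnitude feedback is the identity on the table", {
  set.seed(25)
  g <- feedback_gate(0:1, 4:5, matrix(0.25, 4, 4), pos_node = 0,
                     neg_node = 1, depth = 3, delta_pos = rep(0, 3),
                     delta_neg = rep(0, 3))
  for (k in 1:20) eval_probabilistic(g, sample(0:3, 1))
  P0 <- g$table
  apply_feedback(g, "positive")
  apply_feedback(g, "negative")
  expect_equal(g$table, P0, tolerance = 1e-12)
})

test_that("positive feedback never decreases the credited entry", {
  set.seed(26)
  for (k in 1:200) {
    g <- random_fb_gate()
    i <- sample.int(nrow(g$table), 1) - 1L
    o <- eval_probabilistic(g, i)
    before <- g$table[i + 1, o + 1]
    apply_feedback(g, "positive")
    cap <- min(0.99, 1 - 0.01 * (ncol(g$table) - 1))
    expect_gte(g$table[i + 1, o + 1] + 1e-12, min(before, cap))
    g2 <- random_fb_gate()
    i2 <- sample.int(nrow(g2$table), 1) - 1L
    o2 <- eval_probabilistic(g2, i2)
    before2 <- g2$table[i2 + 1, o2 + 1]
    apply_feedback(g2, "negative")
    expect_lte(g2$table[i2 + 1, o2 + 1] - 1e-12, max(before2, 0.01))
  }
})

test_that("the R and compiled feedback updates agree", {
  set.seed(27)
  for (k in 1:500) {
    K <- sample(2:8, 1)
    row <- runif(K, 0.02, 1)
    row <- row / sum(row)
    o <- sample.int(K, 1)
    u <- runif(1, 0, 0.6)
    sgn <- sample(c(-1L, 1L), 1)
    r_res <- markovbrain:::.apply_one_r(row, o, u, sgn)
    c_res <- markovbrain:::cpp_apply_one(row, o - 1L, u, sgn)
    expect_equal(r_res, c_res, tolerance = 1e-12)
    expect_equal(sum(c_res), 1, tolerance = 1e-9)
  }
})

test_that("feedback line reading distinguishes all four cases", {
  g <- feedback_gate(0, 6, matrix(0.5, 2, 2), pos_node = 8, neg_node = 9)
  states <- integer(16)
  expect_equal(check_feedback_inputs(g, states), "none")
  states[9] <- 1L # node 8
  expect_equal(check_feedback_inputs(g, states), "positive")
  states[9] <- 0L; states[10] <- 1L # node 9
  expect_equal(check_feedback_inputs(g, states), "negative")
  states[9] <- 1L
  expect_equal(check_feedback_inputs(g, states), "both")
})

test_that("gate decoding is total and follows the byte mapping", {
  # all-zero payload: 1 input, 1 output, uniform rows
  span0 <- list(gate_kind = "probabilistic", start = 1L,
                payload = rep(0L, 277))
  g0 <- decode_gate(span0)
  expect_equal(dim(g0$table), c(2, 2))
  expect_equal(g0$table, matrix(0.5, 2, 2))
  # probability decoding: bytes + 1, row-normalized
  payload <- c(0L, 1L, rep(0L, 8), 255L, 0L, 0L, 0L, rep(0L, 263))
  g1 <- decode_gate(list(gate_kind = "probabilistic", start = 1L,
                         payload = payload))
  expect_equal(g1$table[1, ], c(256, 1, 1, 1) / 259, tolerance = 1e-12)
  # feedback extras: depth byte 7 -> depth 4; deltas byte/255
  fp <- rep(0L, 277)
  fp[1:2] <- c(0L, 0L)
  fp[13] <- 7L
  fp[14:17] <- c(255L, 51L, 0L, 102L)
  gf <- decode_gate(list(gate_kind = "feedback", start = 1L, payload = fp))
  expect_equal(gf$depth, 4L)
  expect_equal(gf$delta_pos, c(1, 0.2, 0, 0.4))
  # outputs land only on writable nodes
  set.seed(28)
  for (k in 1:100) {
    sp <- list(gate_kind = sample(c("deterministic", "probabilistic",
                                    "feedback"), 1),
               start = 1L, payload = sample(0:255, 277, TRUE))
    g <- decode_gate(sp)
    expect_true(all(g$output_nodes >= 4 & g$output_nodes <= 15))
    expect_true(all(g$input_nodes >= 0 & g$input_nodes <= 15))
  }
})
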