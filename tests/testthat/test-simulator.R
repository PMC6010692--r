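test_that("default Q-matrix follows the single/double/triple block design", {
  q15 <- default_qmatrix(15)
  expect_equal(dim(q15), c(15L, 5L))
  expect_equal(unname(rowSums(q15)[1:5]), rep(1, 5))
  expect_equal(unname(rowSums(q15)[6:10]), rep(2, 5))
  expect_true(all(rowSums(q15)[11:15] >= 3))
  expect_equal(unname(q15[1:5, ]), diag(5), ignore_attr = TRUE)
  expect_true(all(colSums(q15) >= 3))
  q30 <- default_qmatrix(30)
  expect_equal(unname(q30[16:30, ]), unname(q30[1:15, ]))
  expect_error(default_qmatrix(20), "random_qmatrix")
  expect_error(default_qmatrix(15, K = 4), "random_qmatrix")
})

test_that("Q-matrix validation enforces the binary design contracts", {
  expect_error(as_qmatrix(matrix(c(0, 2), 1)), "0 or 1")
  expect_error(as_qmatrix(rbind(c(1, 0), c(0, 0))), "no attribute")
  expect_warning(as_qmatrix(rbind(c(1, 0), c(1, 0))), "unidentified")
})

test_that("random Q-matrices honour complexity weights, coverage and seeds", {
  q1 <- random_qmatrix(20, 4, c(`1` = 1), seed = 5)
  expect_true(all(rowSums(q1) == 1))
  expect_identical(random_qmatrix(20, 4, seed = 9), random_qmatrix(20, 4, seed = 9))
  for (s in 1:5) {
    q <- random_qmatrix(100, 5, seed = s)
    expect_true(all(colSums(q) > 0))
  }
  expect_error(random_qmatrix(10, 3, c(`7` = 1)), "1..K")
})

test_that("beta mastery draws have the right moments and support", {
  d <- simulate_mastery_beta(10000, 5, 1, 1, seed = 1)
  expect_true(all(abs(colMeans(d) - 0.5) < 0.02))
  expect_true(all(abs(apply(d, 2, var) - 1 / 12) < 0.01))
  d2 <- simulate_mastery_beta(500, 3, 2, 2, seed = 2)
  expect_true(all(d2 > 0 & d2 < 1))
  expect_identical(simulate_mastery_beta(50, 2, 1, 1, seed = 3),
                   simulate_mastery_beta(50, 2, 1, 1, seed = 3))
  expect_error(simulate_mastery_beta(10, 2, -1, 1), "positive")
})

test_that("higher-order mastery generation orders attributes by intercept", {
  ho <- simulate_mastery_higher_order(10000, seed = 4)
  m <- colMeans(ho$delta)
  expect_lt(abs(m[3] - 0.5), 0.02)           # beta_3 = 0: symmetric logistic
  expect_true(all(diff(m) < 0))              # means decrease as beta grows
  expect_equal(dim(ho$delta), c(10000L, 5L))
  # theta = 0 maps to the canonical logistic values
  d0 <- higher_order_mastery_probability(0, rep(1.5, 5), c(-1, -0.5, 0, 0.5, 1))
  expect_equal(round(d0, 3), c(0.731, 0.622, 0.5, 0.378, 0.269))
})

test_that("simulated responses match the generative marginals", {
  q <- default_qmatrix(15)
  # noiseless ceiling: with s = g = 0 and certain mastery every response is 1
  p0 <- model_probability_matrix("pinc", matrix(1, 20, 5), rep(0, 15),
                                 rep(0, 15), q)
  y0 <- matrix(rbinom(length(p0), 1, p0), nrow(p0))
  expect_true(all(y0 == 1))
  # single-attribute item at s = g = 0.1: E[Y] = 0.1 + 0.8 * 0.5 = 0.5
  sim <- simulate_cdm("pinc", 20000, q, "high", seed = 6)
  expect_lt(abs(mean(sim$y[, 1]) - 0.5), 0.01)
  # marginal check for every item: E[rho_i] = (1/2)^(required attributes)
  # under independent uniform mastery
  e_rho <- 0.5^rowSums(q)
  e_y <- 0.1 + 0.8 * e_rho
  expect_true(all(abs(colMeans(sim$y) - e_y) < 0.015))
  expect_identical(simulate_cdm("pinc", 100, q, "high", seed = 7)$y,
                   simulate_cdm("pinc", 100, q, "high", seed = 7)$y)
})

test_that("deterministic-model generation draws profiles before responses", {
  q <- default_qmatrix(15)
  sim <- simulate_cdm("ho-dina", 20000, q, "high", seed = 8)
  expect_true(all(sim$alpha %in% 0:1))
  # alpha_nk ~ Bernoulli(delta_nk): conditional frequencies track delta
  brk <- cut(sim$delta[, 1], c(0, 0.25, 0.5, 0.75, 1))
  freq <- tapply(sim$alpha[, 1], brk, mean)
  mdel <- tapply(sim$delta[, 1], brk, mean)
  expect_true(all(abs(freq - mdel) < 0.03))
  sim2 <- simulate_cdm("dina", 5000, q, "high", pi = c(0.2, 0.4, 0.5, 0.6, 0.8),
                       seed = 9)
  expect_true(all(abs(colMeans(sim2$alpha) - c(0.2, 0.4, 0.5, 0.6, 0.8)) < 0.03))
})
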