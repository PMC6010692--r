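test_that("conjunctive condensation implements the noisy-and gate", {
  expect_equal(conjunctive_condensation(c(1, 1, 0), c(1, 1, 0)), 1L)
  expect_equal(conjunctive_condensation(c(1, 0, 1), c(1, 1, 0)), 0L)
  # empty product convention: an item requiring nothing is always solvable
  expect_equal(conjunctive_condensation(c(0, 0, 0), c(0, 0, 0)), 1L)
  expect_error(conjunctive_condensation(c(1, 0), c(1, 1, 0)), "length")
  expect_error(conjunctive_condensation(c(0.5, 1), c(1, 1)), "binary")
})

test_that("probabilistic latent response is the product over required attributes", {
  expect_equal(probabilistic_latent_response(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_equal(probabilistic_latent_response(c(0.5, 0.5, 0.9), c(1, 1, 0)), 0.25)
  expect_equal(probabilistic_latent_response(c(0.3, 0.3), c(0, 0)), 1)
  expect_error(probabilistic_latent_response(c(1.2, 0.5), c(1, 1)), "\\[0, 1\\]")
  # monotone in required deltas, flat in non-required ones
  base <- probabilistic_latent_response(c(0.4, 0.6, 0.2), c(1, 1, 0))
  expect_gt(probabilistic_latent_response(c(0.5, 0.6, 0.2), c(1, 1, 0)), base)
  expect_equal(probabilistic_latent_response(c(0.4, 0.6, 0.9), c(1, 1, 0)), base)
})

test_that("slip-guess response functions hit their endpoints and range", {
  expect_equal(response_probability_pinc(c(1, 1), c(1, 1), 0.1, 0.1), 0.9)
  expect_equal(response_probability_pinc(c(0.5, 0.5), c(1, 1), 0.1, 0.1), 0.3)
  expect_equal(response_probability_pinc(c(0, 1), c(1, 1), 0.2, 0.2), 0.2)
  expect_equal(response_probability_dina(c(1, 1), c(1, 1), 0.1, 0.2), 0.9)
  expect_equal(response_probability_dina(c(1, 0), c(1, 1), 0.1, 0.2), 0.2)
  expect_error(response_probability_pinc(c(0.5, 0.5), c(1, 1), 0.6, 0.5),
               "monotonicity")
  set.seed(401)
  for (r in 1:20) {
    K <- sample(2:5, 1)
    d <- runif(K); q <- rbinom(K, 1, 0.6)
    s <- runif(1, 0, 0.4); g <- runif(1, 0, min(0.4, 1 - s - 0.01))
    p <- response_probability_pinc(d, q, s, g)
    expect_gte(p, g); expect_lte(p, 1 - s)
  }
})

test_that("the DINA model is the PINC model at binary mastery probabilities", {
  set.seed(402)
  for (r in 1:25) {
    K <- sample(2:6, 1)
    a <- rbinom(K, 1, 0.5); q <- rbinom(K, 1, 0.5)
    s <- runif(1, 0, 0.3); g <- runif(1, 0, 0.3)
    expect_identical(response_probability_dina(a, q, s, g),
                     response_probability_pinc(a, q, s, g))
  }
  # and on whole probability matrices
  q <- default_qmatrix(15)
  alpha <- matrix(rbinom(40 * 5, 1, 0.5), 40, 5)
  s <- rep(0.1, 15); g <- rep(0.15, 15)
  expect_equal(model_probability_matrix("dina", alpha, s, g, q),
               model_probability_matrix("pinc", alpha, s, g, q))
})

test_that("higher-order link is a stable logistic in lambda*theta - beta", {
  expect_equal(higher_order_mastery_probability(0, 1.5, 0), 0.5)
  expect_equal(higher_order_mastery_probability(0, 1.5, -1), plogis(1),
               tolerance = 1e-12)
  expect_equal(higher_order_mastery_probability(0, 1.5, -1), 0.731059,
               tolerance = 1e-6)
  expect_equal(higher_order_mastery_probability(1e6, 1.5, 0), 1)
  expect_equal(higher_order_mastery_probability(-1e6, 1.5, 0), 0)
  expect_error(higher_order_mastery_probability(0, -1, 0), "positive")
  th <- seq(-3, 3, by = 0.5)
  expect_true(all(diff(higher_order_mastery_probability(th, 2, 0.3)) > 0))
})

test_that("log-likelihood matches an independent brute-force double loop", {
  expect_equal(log_likelihood(matrix(c(1, 0), 1), matrix(c(0.5, 0.5), 1)),
               2 * log(0.5))
  # near-certain data: approximately 0 from below
  y1 <- matrix(1L, 3, 4)
  expect_lt(log_likelihood(y1, matrix(1 - 1e-10, 3, 4)), 0)
  expect_gt(log_likelihood(y1, matrix(1 - 1e-10, 3, 4)), -1e-8)
  set.seed(403)
  for (r in 1:10) {
    n <- sample(2:5, 1); i <- sample(2:5, 1)
    y <- matrix(rbinom(n * i, 1, 0.5), n, i)
    if (r > 5) y[sample(length(y), 3)] <- NA  # missing cells contribute 0
    p <- matrix(runif(n * i), n, i)
    expect_equal(log_likelihood(y, p), ll_brute(y, p), tolerance = 1e-12)
  }
  expect_error(log_likelihood(matrix(0, 2, 2), matrix(0.5, 3, 2)), "shape")
})

test_that("model probability matrices respect the [g, 1-s] envelope and links", {
  q <- default_qmatrix(15)
  s <- rep(0.1, 15); g <- rep(0.2, 15)
  # certain mastery: every column constant at 1 - s
  p <- model_probability_matrix("pinc", matrix(1, 10, 5), s, g, q)
  expect_true(all(abs(sweep(p, 2, 1 - s)) < 1e-12))
  # higher-order at theta = 0 with the design generating values
  delta <- higher_order_mastery_probability(0, rep(1.5, 5),
                                            c(-1, -0.5, 0, 0.5, 1))
  expect_equal(round(delta, 3), c(0.731, 0.622, 0.5, 0.378, 0.269))
  ph <- model_probability_matrix("ho-pinc",
                                 list(theta = c(0, 1), lambda = rep(1.5, 5),
                                      beta = c(-1, -0.5, 0, 0.5, 1)),
                                 s, g, q)
  expect_equal(ph[1, 1], g[1] + (1 - s[1] - g[1]) * delta[1])
  set.seed(404)
  dd <- matrix(runif(20 * 5), 20, 5)
  pr <- model_probability_matrix("pinc", dd, s, g, q)
  expect_true(all(pr >= rep(g, each = 20) - 1e-12))
  expect_true(all(pr <= rep(1 - s, each = 20) + 1e-12))
  expect_error(model_probability_matrix("ho-pinc", dd, s, g, q), "theta")
  expect_error(model_probability_matrix("dina", dd, s, g, q), "binary")
})

test_that("HO-PINC collapses to HO-DINA conditional probabilities as slopes grow", {
  q <- default_qmatrix(15)
  s <- rep(0.1, 15); g <- rep(0.1, 15)
  theta <- c(-1.3, -0.2, 0.4, 2.1)
  beta <- c(-1, -0.5, 0, 0.5, 1)
  # at lambda = 50 the logistic link is a step function: delta in {0, 1}
  p_sharp <- model_probability_matrix(
    "ho-pinc", list(theta = theta, lambda = rep(50, 5), beta = beta), s, g, q)
  alpha <- (outer(theta, rep(50, 5)) - rep(beta, each = 4) > 0) * 1
  p_det <- model_probability_matrix("dina", alpha, s, g, q)
  expect_equal(p_sharp, p_det, tolerance = 1e-4)
})
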