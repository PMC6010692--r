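test_that("PSRF matches its closed form and separates chains", {
  # identical chains: B = 0, so PSRF = sqrt((n-1)/n) <= 1
  set.seed(501)
  x <- rnorm(1000)
  expect_lte(psrf(cbind(x, x)), 1.0005)
  expect_equal(psrf(cbind(x, x)), sqrt(999 / 1000), tolerance = 1e-12)
  # same stationary distribution: near 1
  expect_lt(psrf(cbind(rnorm(5000), rnorm(5000))), 1.05)
  # grossly separated chains: dominated by the between-chain term
  expect_gt(psrf(cbind(rnorm(500), rnorm(500, 10))), 1.2)
  expect_warning(r <- psrf(cbind(rep(2, 10), rep(2, 10))), "constant")
  expect_equal(r, 1)
  expect_error(psrf(matrix(rnorm(10), 10, 1)), "two chains")
  expect_error(psrf(list(rnorm(5), rnorm(6))), "equal")
})

test_that("fits are reproducible and respect parameter constraints", {
  tp <- tiny_pinc()
  fit2 <- fit_cdm(tp$sim$y, tp$sim$q, "pinc", control = tiny_ctl(), seed = 12)
  expect_identical(tp$fit$chains[[1]]$delta, fit2$chains[[1]]$delta)
  expect_identical(tp$fit$chains[[2]]$deviance, fit2$chains[[2]]$deviance)
  for (ch in 1:2) {
    s <- tp$fit$chains[[ch]]$s; g <- tp$fit$chains[[ch]]$g
    expect_true(all(g < 1 - s))                      # monotonicity everywhere
    d <- tp$fit$chains[[ch]]$delta
    expect_true(all(d > 0 & d < 1))
  }
  th <- tiny_hopinc()
  for (ch in 1:2) {
    expect_true(all(th$fit$chains[[ch]]$lambda > 0)) # truncated slopes
    expect_true(all(th$fit$chains[[ch]]$g < 1 - th$fit$chains[[ch]]$s))
  }
})

test_that("EAP pooling is the draw average and mastery frequency", {
  tp <- tiny_pinc()
  est <- eap_estimates(tp$fit)
  expect_true(all(c("block", "index", "mean", "sd") %in% names(est)))
  # pooled mean equals the average of per-chain means (equal chain lengths)
  m1 <- colMeans(tp$fit$chains[[1]]$s)
  m2 <- colMeans(tp$fit$chains[[2]]$s)
  expect_equal(unname(eap_matrix(tp$fit, "s")), (m1 + m2) / 2)
  td <- tiny_dina()
  pm <- eap_matrix(td$fit, "alpha")
  expect_true(all(pm >= 0 & pm <= 1))
  # the posterior mastery probability is the mastery draw frequency
  draws <- rbind(td$fit$chains[[1]]$alpha, td$fit$chains[[2]]$alpha)
  expect_equal(unname(pm[1, 1]), mean(draws[, 1]))
})

test_that("a fully masked response matrix returns the mastery prior", {
  y <- matrix(NA_integer_, 25, 15)
  f <- suppressWarnings(
    fit_cdm(y, default_qmatrix(15), "pinc",
            control = cdm_mcmc_control(n_iter = 2000, n_burn = 1000),
            seed = 2))
  d <- as.numeric(rbind(f$chains[[1]]$delta, f$chains[[2]]$delta))
  expect_lt(abs(mean(d) - 0.5), 0.02)        # Beta(1, 1) mean
  expect_lt(abs(var(d) - 1 / 12), 0.01)      # Beta(1, 1) variance
})

test_that("posterior estimates are exchangeable over person order", {
  sim <- simulate_cdm("pinc", 24, default_qmatrix(15), "high", seed = 61)
  ctl <- cdm_mcmc_control(n_iter = 4000, n_burn = 2000)
  f1 <- fit_cdm(sim$y, sim$q, "pinc", control = ctl, seed = 62)
  perm <- rev(seq_len(24))
  f2 <- fit_cdm(sim$y[perm, ], sim$q, "pinc", control = ctl, seed = 63)
  e1 <- eap_matrix(f1, "delta")
  e2 <- eap_matrix(f2, "delta")[order(perm), ]
  expect_gt(cor(as.numeric(e1), as.numeric(e2)), 0.97)
  expect_lt(max(abs(e1 - e2)), 0.12)         # Monte-Carlo error only
})

test_that("convergence report covers every monitored scalar", {
  tp <- tiny_pinc()
  cr <- convergence_report(tp$fit)
  expect_equal(nrow(cr), 60 * 5 + 15 + 15 + 1)   # delta, s, g, deviance
  expect_true(all(cr$psrf >= sqrt((nrow(tp$fit$chains[[1]]$s) - 1) /
                                    nrow(tp$fit$chains[[1]]$s))))
  th <- tiny_hopinc()
  crh <- convergence_report(th$fit)
  expect_equal(nrow(crh), 60 + 5 + 5 + 15 + 15 + 1) # theta, lambda, beta, s, g, D
  f1 <- fit_cdm(tp$sim$y, tp$sim$q, "pinc",
                control = cdm_mcmc_control(n_chains = 1, n_iter = 400,
                                           n_burn = 200), seed = 1)
  expect_error(convergence_report(f1), "two chains")
})

test_that("degenerate response columns warn but do not fail", {
  sim <- simulate_cdm("pinc", 30, default_qmatrix(15), "high", seed = 71)
  y <- sim$y
  y[, 3] <- 1L
  expect_warning(
    fit_cdm(y, sim$q, "pinc", control = tiny_ctl(400, 200), seed = 72),
    "constant")
})

test_that("retained draw counts follow the chain arithmetic", {
  tp <- tiny_pinc()
  ctl <- tp$fit$control
  expect_equal(nrow(tp$fit$chains[[1]]$delta),
               (ctl$n_iter - ctl$n_burn) %/% ctl$n_thin)
  f <- fit_cdm(tp$sim$y, tp$sim$q, "pinc",
               control = cdm_mcmc_control(n_iter = 500, n_burn = 200,
                                          n_thin = 3), seed = 5)
  expect_equal(nrow(f$chains[[1]]$s), 100L)
  expect_error(cdm_mcmc_control(n_iter = 100, n_burn = 100), "n_burn")
})
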