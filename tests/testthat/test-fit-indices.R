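test_that("DIC decomposes as posterior mean deviance plus var(D)/2", {
  d <- dic(c(10, 12))
  expect_equal(d$deviance_mean, 11)
  expect_equal(d$p_d, 1)          # sample variance 2, halved
  expect_equal(d$dic, 12)
  expect_equal(dic(rep(7, 5))$dic, 7)                 # zero variance
  base <- dic(c(3, 5, 8, 1))
  shifted <- dic(c(3, 5, 8, 1) + 100)                 # translation equivariance
  expect_equal(shifted$dic, base$dic + 100)
  expect_equal(shifted$p_d, base$p_d)
  expect_error(dic(5), "at least two")
})

test_that("CPO is the harmonic mean of per-draw cell likelihoods", {
  y <- matrix(1L, 1, 1)
  # single draw: CPO equals that draw's likelihood
  expect_equal(cpo_matrix(y, list(matrix(0.7, 1, 1)))[1, 1], 0.7)
  # two draws with cell likelihoods 0.5 and 0.25: harmonic mean 1/3
  expect_equal(cpo_matrix(y, list(matrix(0.5, 1, 1), matrix(0.25, 1, 1)))[1, 1],
               1 / 3, tolerance = 1e-12)
  # y = 0 uses 1 - p as the cell likelihood
  y0 <- matrix(0L, 1, 1)
  expect_equal(cpo_matrix(y0, list(matrix(0.5, 1, 1), matrix(0.75, 1, 1)))[1, 1],
               1 / 3, tolerance = 1e-12)
  # harmonic-mean bound: CPO never exceeds the best per-draw likelihood
  set.seed(601)
  y2 <- matrix(rbinom(12, 1, 0.5), 3, 4)
  draws <- lapply(1:6, function(m) matrix(runif(12), 3, 4))
  cpo <- cpo_matrix(y2, draws)
  lmax <- Reduce(pmax, lapply(draws, function(p) ifelse(y2 == 1, p, 1 - p)))
  expect_true(all(cpo <= lmax + 1e-12))
  # missing cells propagate as NA
  y2[1, 1] <- NA
  expect_true(is.na(cpo_matrix(y2, draws)[1, 1]))
  expect_error(cpo_matrix(y2, list()), "at least one")
})

test_that("-2LCPO aggregates items into the test level", {
  ones <- matrix(1, 10, 2)
  expect_equal(lcpo_summaries(ones)$test, 0)
  half <- matrix(0.5, 10, 2)
  l <- lcpo_summaries(half)
  expect_equal(unname(l$items), rep(-2 * 10 * log(0.5), 2))
  expect_equal(l$test, sum(l$items))
  expect_error(lcpo_summaries(matrix(c(0.5, -0.1), 1)), "\\(0, 1\\]")
})

test_that("fit_indices satisfies its identities on a real fit", {
  tp <- tiny_pinc()
  fi <- fit_indices(tp$fit, max_cpo_draws = 200)
  s <- fi$summary
  dev <- c(tp$fit$chains[[1]]$deviance, tp$fit$chains[[2]]$deviance)
  expect_equal(s$dic, mean(dev) + var(dev) / 2)       # exact identity
  expect_gte(s$p_d, 0)
  expect_equal(s$minus2_lcpo_test, sum(fi$lcpo_items$minus2_lcpo))
  # plug-in deviance is below the posterior mean deviance (Jensen direction)
  expect_lt(s$deviance_at_posterior_mean, s$deviance_mean)
  # replayer and explicit draw list give the same CPO
  replay <- pincdm:::prob_replayer(tp$fit)
  cpo_fun <- cpo_matrix(tp$sim$y, replay, n_draws = 50)
  cpo_list <- cpo_matrix(tp$sim$y, lapply(1:50, replay))
  expect_equal(cpo_fun, cpo_list, tolerance = 1e-12)
})

test_that("tidy and glance summarise a fit in broom shape", {
  tp <- tiny_pinc()
  td <- tidy(tp$fit)
  expect_true(all(c("term", "estimate", "std.error", "psrf") %in% names(td)))
  expect_equal(nrow(td), 60 * 5 + 15 + 15)
  expect_true(all(td$estimate[td$block %in% c("delta", "s", "g")] > 0))
  gl <- glance(tp$fit)
  expect_equal(gl$n_draws, 2 * 400)
  expect_equal(gl$dic, gl$deviance_mean + gl$p_d)
  th <- tiny_hopinc()
  tdh <- tidy(th$fit)
  expect_true(any(tdh$block == "theta"))
  expect_equal(sum(tdh$block == "lambda"), 5)
})
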