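test_that("rmse and pearson_cor match their textbook definitions", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 1), c(1, 0)), 1)
  set.seed(701)
  tr <- rnorm(100); es <- tr + rnorm(100, 0, 0.3)
  brute <- sqrt(sum((es - tr)^2) / 100)                 # independent loop-free oracle
  expect_equal(rmse(tr, es), brute, tolerance = 1e-14)
  expect_equal(pearson_cor(tr, 2 * tr + 1), 1)
  expect_equal(pearson_cor(tr, -tr), -1)
  num <- sum((tr - mean(tr)) * (es - mean(es)))
  den <- sqrt(sum((tr - mean(tr))^2) * sum((es - mean(es))^2))
  expect_equal(pearson_cor(tr, es), num / den, tolerance = 1e-12)
  expect_warning(r <- pearson_cor(tr, rep(1, 100)), "constant")
  expect_true(is.na(r))
  expect_error(rmse(1:3, 1:4), "equal-length")
})

test_that("a single-replication recovery run is deterministic and well-shaped", {
  ctl <- cdm_mcmc_control(n_iter = 600, n_burn = 300)
  r1 <- recovery_condition("pinc", N = 60, I = 15, item_quality = "high",
                           replications = 1, control = ctl, base_seed = 42)
  r2 <- recovery_condition("pinc", N = 60, I = 15, item_quality = "high",
                           replications = 1, control = ctl, base_seed = 42)
  expect_identical(r1$results, r2$results)
  res <- r1$results
  delta_rmse <- dplyr::filter(res, parameter == "delta", statistic == "rmse",
                              aggregation == "pooled")
  expect_equal(nrow(delta_rmse), 5)                    # one row per attribute
  expect_true(all(delta_rmse$value >= 0))
  cors <- dplyr::filter(res, statistic == "cor")$value
  expect_true(all(abs(cors) <= 1))
  # with one replication the pooled and replication-mean summaries coincide
  w <- tidyr::pivot_wider(dplyr::filter(res, parameter == "delta"),
                          id_cols = c("index", "statistic"),
                          names_from = "aggregation", values_from = "value")
  expect_equal(w$pooled[w$statistic == "rmse"], w$rep_mean[w$statistic == "rmse"],
               tolerance = 1e-12)
  expect_equal(nrow(dplyr::filter(res, parameter %in% c("s", "g"))), 30)
})

test_that("higher-order conditions also score the latent trait", {
  ctl <- cdm_mcmc_control(n_iter = 600, n_burn = 300)
  r <- recovery_condition("ho-pinc", N = 60, I = 15, replications = 1,
                          control = ctl, base_seed = 43)
  th <- dplyr::filter(r$results, parameter == "theta")
  expect_equal(nrow(th), 4)                            # rmse/cor x two aggregations
  expect_true(all(th$value[th$statistic == "cor"] > 0))
})

test_that("condition grids enumerate the full design and propagate seeds", {
  g <- condition_grid("pinc", replications = 5)
  expect_equal(nrow(g), 8)                             # 2 N x 2 I x 2 IQ
  expect_equal(sort(unique(g$N)), c(500, 1000))
  g1 <- condition_grid("pinc", N = 60, I = 15, item_quality = "high",
                       replications = 1)
  ctl <- cdm_mcmc_control(n_iter = 600, n_burn = 300)
  grid <- run_recovery_grid(g1, control = ctl, base_seed = 42)
  single <- recovery_condition("pinc", N = 60, I = 15, item_quality = "high",
                               replications = 1, control = ctl, base_seed = 42,
                               condition_id = 1)
  expect_equal(grid$results, single$results)
  expect_length(grid$failures, 0)
})
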