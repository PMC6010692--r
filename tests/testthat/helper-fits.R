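# Small fitted models reused across test files; built once per test run.
.fit_cache <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.fit_cache[[key]])) assign(key, fn(), envir = .fit_cache)
  get(key, envir = .fit_cache)
}

tiny_ctl <- function(n_iter = 800, n_burn = 400) {
  cdm_mcmc_control(n_iter = n_iter, n_burn = n_burn)
}

tiny_pinc <- function() cached("pinc", function() {
  sim <- simulate_cdm("pinc", 60, default_qmatrix(15), "high", seed = 11)
  list(sim = sim,
       fit = fit_cdm(sim$y, sim$q, "pinc", control = tiny_ctl(), seed = 12))
})

tiny_hopinc <- function() cached("hopinc", function() {
  sim <- simulate_cdm("ho-pinc", 60, default_qmatrix(15), "high", seed = 21)
  list(sim = sim,
       fit = fit_cdm(sim$y, sim$q, "ho-pinc", control = tiny_ctl(), seed = 22))
})

tiny_dina <- function() cached("dina", function() {
  sim <- simulate_cdm("dina", 60, default_qmatrix(15), "high", seed = 31)
  list(sim = sim,
       fit = fit_cdm(sim$y, sim$q, "dina", control = tiny_ctl(), seed = 32))
})

# independently coded cell-by-cell Bernoulli log-likelihood (oracle)
ll_brute <- function(y, p) {
  tot <- 0
  for (n in seq_len(nrow(y))) {
    for (i in seq_len(ncol(y))) {
      if (is.na(y[n, i])) next
      pp <- min(max(p[n, i], 1e-10), 1 - 1e-10)
      tot <- tot + if (y[n, i] == 1) log(pp) else log(1 - pp)
    }
  }
  tot
}
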