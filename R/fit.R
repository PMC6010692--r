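#' Prior specification for the conjunctive diagnosis models
#'
#' Defaults follow the non-informative setup used for Bayesian estimation of
#' these models: `delta_nk ~ Beta(1, 1)`, `s_i ~ Beta(1, 1)` and
#' `g_i ~ Beta(1, 1)` truncated to the monotone region `g_i < 1 - s_i`; for
#' the higher-order variants `theta_n ~ N(0, 1)` (fixed, for identification),
#' `lambda_k ~ N(0, 4) I(lambda_k > 0)` and `beta_k ~ N(0, 4)`, where 4 is a
#' variance (`lambda_sd = beta_sd = 2`). The DINA base rates use
#' `pi_k ~ Beta(1, 1)`.
#'
#' @param delta_shape,slip_shape,guess_shape,pi_shape length-2 beta shapes.
#' @param lambda_sd,beta_sd normal prior standard deviations for the
#'   higher-order slopes (truncated positive) and intercepts.
#' @return A `cdm_priors` list.
#' @export
cdm_priors <- function(delta_shape = c(1, 1), slip_shape = c(1, 1),
                       guess_shape = c(1, 1), pi_shape = c(1, 1),
                       lambda_sd = 2, beta_sd = 2) {
  shapes <- list(delta = delta_shape, slip = slip_shape, guess = guess_shape,
                 pi = pi_shape)
  for (nm in names(shapes)) {
    if (length(shapes[[nm]]) != 2 || any(shapes[[nm]] <= 0)) {
      stop(nm, "_shape must be two positive beta shape parameters",
           call. = FALSE)
    }
  }
  if (lambda_sd <= 0 || beta_sd <= 0) {
    stop("prior standard deviations must be positive", call. = FALSE)
  }
  structure(list(delta_shape = delta_shape, slip_shape = slip_shape,
                 guess_shape = guess_shape, pi_shape = pi_shape,
                 lambda_sd = lambda_sd, beta_sd = beta_sd),
            class = "cdm_priors")
}

#' MCMC run configuration
#'
#' Defaults match the estimation protocol of the recovery studies: 2 chains of
#' 10,000 iterations with the first 5,000 as burn-in and no thinning, leaving
#' `n_chains * (n_iter - n_burn) / n_thin` retained draws. Random-walk
#' proposal scales adapt in batches of `adapt_batch` iterations during burn-in
#' toward the target acceptance band, then freeze.
#'
#' @param n_chains number of independent chains (>= 2 for convergence
#'   diagnostics).
#' @param n_iter,n_burn,n_thin iterations per chain, burn-in length, thinning.
#' @param adapt_batch burn-in adaptation batch size.
#' @param target_accept length-2 acceptance band for scalar random walks.
#' @param store_person keep the person-level draws (`delta` or `alpha`)?
#'   Needed for EAP mastery estimates and CPO; turn off to save memory on
#'   very long runs where only the structural parameters matter.
#' @return A `cdm_mcmc_control` list.
#' @export
cdm_mcmc_control <- function(n_chains = 2, n_iter = 10000, n_burn = 5000,
                             n_thin = 1, adapt_batch = 50,
                             target_accept = c(0.30, 0.45),
                             store_person = TRUE) {
  if (n_burn >= n_iter) stop("n_burn must be smaller than n_iter", call. = FALSE)
  if (n_chains < 1 || n_thin < 1) stop("invalid chain/thinning setup", call. = FALSE)
  if (length(target_accept) != 2 || target_accept[1] >= target_accept[2]) {
    stop("target_accept must be an increasing length-2 band", call. = FALSE)
  }
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burn = as.integer(n_burn), n_thin = as.integer(n_thin),
                 adapt_batch = as.integer(adapt_batch),
                 target_accept = target_accept,
                 store_person = isTRUE(store_person)),
            class = "cdm_mcmc_control")
}

#' Fit a conjunctive cognitive diagnosis model by MCMC
#'
#' Metropolis-within-Gibbs estimation of the PINC, HO-PINC, DINA or HO-DINA
#' model. Per sweep: mastery probabilities `delta_nk` (PINC) move by
#' random-walk Metropolis on the logit scale; binary profiles `alpha_nk`
#' (DINA variants) are drawn exactly from their two-point full conditionals;
#' higher-order `theta_n`, `lambda_k` (rejected at 0) and `beta_k` move by
#' random walks; and each `(s_i, g_i)` moves by random walks with proposals
#' violating `g < 1 - s` rejected, which is equivalent to the truncated prior.
#' Chains start from independent prior draws and the deviance
#' `-2 log L` is recorded at every retained iteration.
#'
#' @param y binary response matrix (persons x items; `NA` = missing).
#' @param q Q-matrix (items x attributes).
#' @param model `"pinc"`, `"ho-pinc"`, `"dina"` or `"ho-dina"`.
#' @param priors a [cdm_priors()] specification.
#' @param control a [cdm_mcmc_control()] configuration.
#' @param seed integer base seed; chain `c` runs under
#'   [child_seed()]`(seed, c)`, so single chains are reproducible in
#'   isolation.
#' @return A `cdm_fit` object: retained draws per chain (matrices with one
#'   row per retained iteration), acceptance rates, the data, and the run
#'   configuration. Use [tidy()] / [glance()] / [eap_estimates()] /
#'   [convergence_report()] / [fit_indices()] on it.
#' @export
fit_cdm <- function(y, q, model = c("pinc", "ho-pinc", "dina", "ho-dina"),
                    priors = cdm_priors(), control = cdm_mcmc_control(),
                    seed = 1) {
  model <- match_model(model[1])
  q <- as_qmatrix(q)
  y <- as_response_matrix(y, q)
  stopifnot(inherits(priors, "cdm_priors"), inherits(control, "cdm_mcmc_control"))

  col_obs <- colMeans(y, na.rm = TRUE)
  degenerate <- which(!is.na(col_obs) & (col_obs == 0 | col_obs == 1))
  if (length(degenerate)) {
    warning("response column(s) ", paste(degenerate, collapse = ", "),
            " are constant; the corresponding item parameters are weakly ",
            "identified", call. = FALSE)
  }

  y_c <- y
  y_c[is.na(y_c)] <- -1L
  args <- list(Y = y_c, Q = q,
               a_s = priors$slip_shape[1], b_s = priors$slip_shape[2],
               a_g = priors$guess_shape[1], b_g = priors$guess_shape[2],
               n_iter = control$n_iter, n_burn = control$n_burn,
               n_thin = control$n_thin, adapt_batch = control$adapt_batch,
               acc_lo = control$target_accept[1],
               acc_hi = control$target_accept[2],
               store_person = control$store_person)
  fun <- switch(model,
    "pinc" = function(a) do.call(cpp_chain_pinc, c(
      a, list(a_delta = priors$delta_shape[1], b_delta = priors$delta_shape[2]))),
    "ho-pinc" = function(a) do.call(cpp_chain_hopinc, c(
      a, list(lambda_sd = priors$lambda_sd, beta_sd = priors$beta_sd))),
    "dina" = function(a) do.call(cpp_chain_dina, c(
      a, list(a_pi = priors$pi_shape[1], b_pi = priors$pi_shape[2]))),
    "ho-dina" = function(a) do.call(cpp_chain_hodina, c(
      a, list(lambda_sd = priors$lambda_sd, beta_sd = priors$beta_sd))))

  chain_seeds <- vapply(seq_len(control$n_chains),
                        function(ch) child_seed(seed, ch), integer(1))
  chains <- vector("list", control$n_chains)
  for (ch in seq_len(control$n_chains)) {
    set.seed(chain_seeds[ch])
    chains[[ch]] <- fun(args)
  }

  structure(list(model = model, y = y, q = q, chains = chains,
                 priors = priors, control = control,
                 seed = seed, chain_seeds = chain_seeds,
                 N = nrow(y), I = ncol(y), K = ncol(q)),
            class = "cdm_fit")
}

#' @export
print.cdm_fit <- function(x, ...) {
  cat("Bayesian", toupper(x$model), "fit:",
      x$N, "persons x", x$I, "items,", x$K, "attributes\n")
  cat(x$control$n_chains, "chains x", x$control$n_iter, "iterations (",
      x$control$n_burn, "burn-in, thin", x$control$n_thin, ") ->",
      x$control$n_chains * n_retained(x), "retained draws\n")
  dic <- dic(pooled_draws(x, "deviance"))
  cat("posterior mean deviance", format(dic$deviance_mean, digits = 6),
      " DIC", format(dic$dic, digits = 6), "\n")
  invisible(x)
}

n_retained <- function(fit) {
  (fit$control$n_iter - fit$control$n_burn) %/% fit$control$n_thin
}

# names of the per-chain draw blocks available for a model
draw_blocks <- function(fit) {
  blocks <- names(fit$chains[[1]])
  setdiff(blocks, "acceptance")
}

# person-level block name ("delta" for probabilistic, "alpha" for
# deterministic variants)
person_block <- function(fit) if (is_probabilistic(fit$model)) "delta" else "alpha"

# draws of one block from one chain, as a matrix (retained x scalars)
chain_draws <- function(fit, block, chain = 1) {
  d <- fit$chains[[chain]][[block]]
  if (is.null(d)) stop("no draws stored for block '", block, "'", call. = FALSE)
  d <- as.matrix(d)
  if (block %in% c("delta", "alpha") && ncol(d) == 0) {
    stop("person-level draws were not stored (store_person = FALSE)",
         call. = FALSE)
  }
  d
}

# pooled draws across chains
pooled_draws <- function(fit, block) {
  do.call(rbind, lapply(seq_along(fit$chains),
                        function(ch) chain_draws(fit, block, ch)))
}

#' Posterior means and standard deviations (EAP estimates)
#'
#' Pools the retained draws across chains and returns the expected a
#' posteriori estimate and posterior standard deviation of every monitored
#' scalar. For the deterministic variants the `alpha` rows are posterior
#' mastery probabilities `P(alpha_nk = 1)`, i.e. the mastery draw frequencies.
#'
#' @param fit a [fit_cdm()] result.
#' @return A tibble with columns `block`, `index` (within-block column),
#'   `mean`, `sd`.
#' @export
eap_estimates <- function(fit) {
  stopifnot(inherits(fit, "cdm_fit"))
  blocks <- setdiff(draw_blocks(fit), "deviance")
  purrr::map_dfr(blocks, function(b) {
    d <- pooled_draws(fit, b)
    tibble::tibble(block = b, index = seq_len(ncol(d)),
                   mean = colMeans(d), sd = apply(d, 2, sd))
  })
}

#' EAP estimate of one parameter block in its natural shape
#'
#' @param fit a [fit_cdm()] result.
#' @param block `"delta"`, `"alpha"`, `"theta"`, `"lambda"`, `"beta"`, `"s"`,
#'   `"g"` or `"pi"` (availability depends on the model).
#' @return A vector, or an N x K matrix for the person-level blocks.
#' @export
eap_matrix <- function(fit, block) {
  d <- colMeans(pooled_draws(fit, block))
  if (block %in% c("delta", "alpha")) {
    matrix(d, fit$N, fit$K, dimnames = list(rownames(fit$y), colnames(fit$q)))
  } else {
    d
  }
}
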