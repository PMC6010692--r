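#' Deviance information criterion
#'
#' From the per-iteration deviance draws `D = -2 log L`: the posterior mean
#' deviance `D_bar`, the effective number of parameters `p_D = var(D) / 2`
#' (sample variance, denominator M - 1), and `DIC = D_bar + p_D`. Smaller is
#' better.
#'
#' @param deviance_draws numeric vector of retained deviance values (M >= 2).
#' @return A list with `deviance_mean`, `p_d`, `dic`.
#' @export
dic <- function(deviance_draws) {
  deviance_draws <- as.numeric(deviance_draws)
  if (length(deviance_draws) < 2) {
    stop("DIC needs at least two deviance draws", call. = FALSE)
  }
  d_bar <- mean(deviance_draws)
  p_d <- var(deviance_draws) / 2
  list(deviance_mean = d_bar, p_d = p_d, dic = d_bar + p_d)
}

# elementwise log(exp(a) + exp(b)) with -Inf handled
pairwise_lse <- function(a, b) {
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  out <- hi + log1p(exp(lo - hi))
  out[is.infinite(hi)] <- hi[is.infinite(hi)]
  out
}

#' Conditional predictive ordinate matrix
#'
#' The harmonic-mean CPO estimator per response cell:
#' `CPO_ni = [ (1/M) * sum_m 1 / L_ni(m) ]^{-1}`, where `L_ni(m)` is the
#' Bernoulli likelihood of cell (n, i) under draw m. Accumulated in log space
#' (streaming log-sum-exp of the negative cell log-likelihoods), with
#' probabilities clamped into `[1e-10, 1 - 1e-10]`.
#'
#' @param y binary response matrix (`NA` = missing; missing cells return
#'   `NA`).
#' @param prob_draws per-draw probability matrices: a list of N x I matrices,
#'   an N x I x M array, or a replayer `function(m)` returning the m-th
#'   matrix.
#' @param n_draws number of draws; required when `prob_draws` is a function.
#' @return An N x I matrix of CPO values in (0, 1].
#' @export
cpo_matrix <- function(y, prob_draws, n_draws = NULL) {
  y <- as_response_matrix(y)
  if (is.function(prob_draws)) {
    if (is.null(n_draws)) stop("n_draws is required with a replayer", call. = FALSE)
    getp <- prob_draws
    M <- n_draws
  } else if (is.array(prob_draws) && length(dim(prob_draws)) == 3) {
    getp <- function(m) prob_draws[, , m]
    M <- dim(prob_draws)[3]
  } else if (is.list(prob_draws)) {
    getp <- function(m) prob_draws[[m]]
    M <- length(prob_draws)
  } else {
    stop("prob_draws must be a list, 3-d array or replayer function",
         call. = FALSE)
  }
  if (M < 1) stop("CPO needs at least one retained draw", call. = FALSE)
  eps <- 1e-10
  obs <- !is.na(y)
  yy <- y
  yy[!obs] <- 0L
  # running log-sum-exp of -log L_ni over draws
  acc <- matrix(-Inf, nrow(y), ncol(y))
  for (m in seq_len(M)) {
    p <- pmin(pmax(getp(m), eps), 1 - eps)
    if (!all(dim(p) == dim(y))) {
      stop("draw ", m, " has shape ", paste(dim(p), collapse = "x"),
           ", expected ", paste(dim(y), collapse = "x"), call. = FALSE)
    }
    nll <- -(yy * log(p) + (1 - yy) * log1p(-p))
    acc <- pairwise_lse(acc, nll)
  }
  cpo <- exp(log(M) - acc)
  cpo[!obs] <- NA_real_
  cpo
}

#' Test- and item-level -2LCPO
#'
#' Item level: `-2 * sum_n log CPO_ni` over observed cells; test level: the
#' sum over items. Smaller values indicate better predictive fit.
#'
#' @param cpo an N x I CPO matrix from [cpo_matrix()].
#' @return A list with `test` (scalar) and `items` (length-I vector).
#' @export
lcpo_summaries <- function(cpo) {
  cpo <- as.matrix(cpo)
  vals <- cpo[!is.na(cpo)]
  if (any(vals <= 0) || any(vals > 1)) {
    stop("CPO values must lie in (0, 1]", call. = FALSE)
  }
  items <- -2 * colSums(log(cpo), na.rm = TRUE)
  list(test = sum(items), items = items)
}

# replays pooled posterior draws as per-draw probability matrices
prob_replayer <- function(fit) {
  person <- pooled_draws(fit, person_block(fit))
  s <- pooled_draws(fit, "s")
  g <- pooled_draws(fit, "g")
  q <- fit$q
  N <- fit$N
  K <- fit$K
  function(m) {
    pm <- matrix(person[m, ], N, K)
    rho <- latent_response_matrix(pm, q)
    sweep(rho, 2, 1 - s[m, ] - g[m, ], `*`) + rep(g[m, ], each = N)
  }
}

# plug-in probability matrix at the posterior-mean parameters. For the
# deterministic variants the posterior mastery probabilities are plugged into
# the marginal (product) algebra, which equals the conditional response
# probability marginal over independent Bernoulli attribute draws.
plugin_prob <- function(fit) {
  person <- eap_matrix(fit, person_block(fit))
  rho <- latent_response_matrix(person, fit$q)
  s <- eap_matrix(fit, "s")
  g <- eap_matrix(fit, "g")
  sweep(rho, 2, 1 - s - g, `*`) + rep(g, each = fit$N)
}

#' Model-fit index report
#'
#' Computes, from a fitted model's retained draws: the posterior mean deviance
#' `D_bar`; the plug-in deviance at the posterior-mean parameters (labelled
#' separately since "-2LL" conventions differ); the effective parameter counts
#' `p_D = var(D)/2` (headline) and `D_bar - D(posterior mean)` (plug-in
#' variant); the two DICs; and the -2LCPO at test and item level via the
#' harmonic-mean CPO.
#'
#' @param fit a [fit_cdm()] result with stored person-level draws.
#' @param max_cpo_draws cap on the number of pooled draws replayed for the
#'   CPO (evenly subsampled above the cap) to bound the cost on long runs;
#'   `Inf` uses every retained draw.
#' @return A `cdm_fit_indices` list: `summary` (one-row tibble) and
#'   `lcpo_items` (tibble of item-level -2LCPO).
#' @export
fit_indices <- function(fit, max_cpo_draws = 2000) {
  stopifnot(inherits(fit, "cdm_fit"))
  dev <- as.numeric(pooled_draws(fit, "deviance"))
  d <- dic(dev)
  d_plugin <- -2 * log_likelihood(fit$y, plugin_prob(fit))
  p_d_plugin <- d$deviance_mean - d_plugin

  replay <- prob_replayer(fit)
  M <- length(dev)
  idx <- if (M > max_cpo_draws) {
    unique(round(seq(1, M, length.out = max_cpo_draws)))
  } else {
    seq_len(M)
  }
  cpo <- cpo_matrix(fit$y, function(m) replay(idx[m]), n_draws = length(idx))
  lcpo <- lcpo_summaries(cpo)

  structure(list(
    summary = tibble::tibble(
      model = fit$model,
      deviance_mean = d$deviance_mean,
      deviance_at_posterior_mean = d_plugin,
      p_d = d$p_d,
      dic = d$dic,
      p_d_plugin = p_d_plugin,
      dic_plugin = d_plugin + 2 * p_d_plugin,
      minus2_lcpo_test = lcpo$test,
      n_draws = M),
    lcpo_items = tibble::tibble(item = colnames(fit$y) %||% seq_along(lcpo$items),
                                minus2_lcpo = lcpo$items)),
    class = "cdm_fit_indices")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cdm_fit_indices <- function(x, ...) {
  s <- x$summary
  cat("Fit indices (", toupper(s$model), "):\n", sep = "")
  cat("  posterior mean deviance ", format(s$deviance_mean, digits = 6),
      "   deviance at posterior mean ", format(s$deviance_at_posterior_mean,
                                               digits = 6), "\n", sep = "")
  cat("  p_D = var(D)/2 = ", format(s$p_d, digits = 4),
      "   DIC = ", format(s$dic, digits = 6), "\n", sep = "")
  cat("  -2LCPO (test level) = ", format(s$minus2_lcpo_test, digits = 6),
      "\n", sep = "")
  invisible(x)
}
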