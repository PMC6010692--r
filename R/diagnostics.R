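#' Potential scale reduction factor (Brooks-Gelman)
#'
#' Univariate PSRF for one scalar parameter monitored in two or more chains of
#' equal retained length n. With W the mean within-chain variance and
#' `var_means` the variance of the chain means, the estimator is
#' `sqrt(((n - 1) / n) * W + var_means) / sqrt(W)`, bounded below by
#' `sqrt((n - 1) / n)`. Values near 1 indicate between-chain agreement;
#' 1.1 or 1.2 are the customary convergence cutoffs.
#'
#' @param x a matrix with one column per chain, or a list of equal-length
#'   draw vectors.
#' @return The PSRF. A parameter with zero within-chain variance in every
#'   chain returns 1 with a warning (constant parameter).
#' @export
psrf <- function(x) {
  if (is.list(x)) {
    len <- lengths(x)
    if (length(unique(len)) != 1) {
      stop("chains must have equal retained length", call. = FALSE)
    }
    x <- do.call(cbind, x)
  }
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("PSRF needs at least two chains", call. = FALSE)
  n <- nrow(x)
  if (n < 2) stop("PSRF needs at least two retained draws", call. = FALSE)
  w <- mean(apply(x, 2, var))
  if (w == 0) {
    warning("zero within-chain variance (constant parameter); PSRF set to 1",
            call. = FALSE)
    return(1)
  }
  var_means <- var(colMeans(x))
  sqrt(((n - 1) / n) * w + var_means) / sqrt(w)
}

# PSRF for every column of a draw block, vectorized over scalars
block_psrf <- function(fit, block) {
  chains <- lapply(seq_along(fit$chains), function(ch) chain_draws(fit, block, ch))
  n <- nrow(chains[[1]])
  m <- length(chains)
  means <- sapply(chains, colMeans)            # scalars x chains
  vars <- sapply(chains, function(d) apply(d, 2, var))
  if (is.null(dim(means))) {                   # single-scalar block
    means <- matrix(means, nrow = 1)
    vars <- matrix(vars, nrow = 1)
  }
  w <- rowMeans(vars)
  var_means <- apply(means, 1, var)
  out <- sqrt(((n - 1) / n) * w + var_means) / sqrt(w)
  out[w == 0] <- 1
  out
}

# the parameter blocks monitored for convergence, per model
monitored_blocks <- function(fit) {
  switch(fit$model,
    "pinc"    = c("delta", "s", "g", "deviance"),
    "ho-pinc" = c("theta", "lambda", "beta", "s", "g", "deviance"),
    "dina"    = c("pi", "s", "g", "deviance"),
    "ho-dina" = c("theta", "lambda", "beta", "s", "g", "deviance"))
}

#' Per-parameter convergence report
#'
#' Computes the Brooks-Gelman PSRF for every monitored scalar — the mastery
#' probabilities `delta` (or the higher-order `theta`, `lambda`, `beta`; or
#' the DINA base rates `pi`), the item parameters `s` and `g`, and the
#' deviance — and flags parameters at or above the threshold.
#'
#' @param fit a [fit_cdm()] result with at least two chains.
#' @param threshold convergence cutoff (default 1.2; 1.1 is stricter).
#' @return A tibble with columns `block`, `index`, `psrf`, `converged`.
#' @export
convergence_report <- function(fit, threshold = 1.2) {
  stopifnot(inherits(fit, "cdm_fit"))
  if (fit$control$n_chains < 2) {
    stop("convergence_report() needs at least two chains", call. = FALSE)
  }
  blocks <- monitored_blocks(fit)
  if (!fit$control$store_person) blocks <- setdiff(blocks, c("delta", "alpha"))
  purrr::map_dfr(blocks, function(b) {
    r <- block_psrf(fit, b)
    tibble::tibble(block = b, index = seq_along(r), psrf = r,
                   converged = r < threshold)
  })
}

#' Has a fit converged?
#'
#' @inheritParams convergence_report
#' @return `TRUE` if the maximum PSRF over all monitored scalars is below the
#'   threshold.
#' @export
converged <- function(fit, threshold = 1.2) {
  all(convergence_report(fit, threshold)$converged)
}
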