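#' Item-quality presets
#'
#' Expands an item-quality label or explicit vectors into per-item slip and
#' guessing vectors. `"high"` sets `s_i = g_i = 0.1` (diagnostic information
#' `1 - s - g = 0.8`), `"low"` sets `s_i = g_i = 0.2`.
#'
#' @param item_quality `"high"`, `"low"`, or a list with numeric `slip` and
#'   `guess` elements (scalars are recycled).
#' @param I number of items.
#' @return A list with `slip` and `guess` vectors of length `I`.
#' @export
item_quality_params <- function(item_quality, I) {
  if (is.character(item_quality)) {
    sg <- switch(match.arg(item_quality, c("high", "low")), high = 0.1, low = 0.2)
    out <- list(slip = rep(sg, I), guess = rep(sg, I))
  } else if (is.list(item_quality)) {
    out <- list(slip = rep_len(item_quality$slip, I),
                guess = rep_len(item_quality$guess, I))
  } else {
    stop("item_quality must be \"high\", \"low\" or list(slip=, guess=)",
         call. = FALSE)
  }
  check_item_params(out$slip, out$guess, I)
  out
}

#' Simulate independent mastery probabilities
#'
#' Draws the N x K mastery-probability matrix `delta` i.i.d. from
#' `Beta(a, b)`; the default `Beta(1, 1)` is the uniform generating
#' distribution of the independent-attribute simulation design.
#'
#' @param N,K person and attribute counts.
#' @param a,b beta shape parameters, both positive.
#' @param seed optional integer seed.
#' @return An N x K matrix of probabilities.
#' @export
simulate_mastery_beta <- function(N, K, a = 1, b = 1, seed = NULL) {
  if (a <= 0 || b <= 0) stop("beta shapes must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  matrix(rbeta(N * K, a, b), N, K,
         dimnames = list(NULL, paste0("attr", seq_len(K))))
}

#' Simulate higher-order mastery probabilities
#'
#' Draws `theta_n ~ N(0, 1)` and maps it through the logistic link
#' `delta_nk = plogis(lambda_k * theta_n - beta_k)`. The default slopes and
#' intercepts are the generating values of the higher-order simulation design:
#' `lambda_k = 1.5` for all attributes and intercepts `(-1, -0.5, 0, 0.5, 1)`,
#' which order the attributes from easiest to hardest to master.
#'
#' @param N person count.
#' @param lambda attribute slopes (> 0).
#' @param beta attribute intercepts, same length as `lambda`.
#' @param seed optional integer seed.
#' @return A list with `theta` (length N) and `delta` (N x K).
#' @export
simulate_mastery_higher_order <- function(N, lambda = rep(1.5, 5),
                                          beta = c(-1, -0.5, 0, 0.5, 1),
                                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  theta <- rnorm(N)
  delta <- outer_delta(theta, lambda, beta)
  colnames(delta) <- paste0("attr", seq_along(lambda))
  list(theta = theta, delta = delta)
}

#' Simulate item responses under a conjunctive diagnosis model
#'
#' Generates a complete dataset (responses plus the generating truth) under
#' any of the four model variants:
#'
#' * `"pinc"`: `delta ~ Beta(a, b)` i.i.d., responses
#'   `Y ~ Bernoulli(g + (1 - s - g) * prod_k delta_k^q_k)`.
#' * `"ho-pinc"`: `theta ~ N(0, 1)` mapped to `delta` by the logistic link,
#'   then the same response function.
#' * `"dina"`: binary profiles `alpha ~ Bernoulli(pi_k)` (default
#'   `pi_k = 0.5`), responses through the conjunctive rule.
#' * `"ho-dina"`: `theta ~ N(0, 1)`, `alpha_nk ~ Bernoulli(delta_nk)` with
#'   `delta` from the logistic link, then the conjunctive rule.
#'
#' @param model model tag.
#' @param N person count.
#' @param q Q-matrix (e.g. [default_qmatrix()]).
#' @param item_quality `"high"` (`s = g = 0.1`), `"low"` (`s = g = 0.2`) or
#'   `list(slip=, guess=)`.
#' @param beta_shape length-2 vector `(a, b)` for the PINC mastery prior.
#' @param lambda,beta higher-order generating slopes and intercepts.
#' @param pi attainment base rates for `"dina"` profiles.
#' @param seed integer seed; the simulation is a pure function of its
#'   arguments and this seed.
#' @return A `cdm_sim` list with elements `y` (N x I response matrix), `q`,
#'   `model`, `slip`, `guess`, and the generating person parameters
#'   (`delta`, and `theta` / `alpha` where applicable).
#' @export
simulate_cdm <- function(model, N, q = default_qmatrix(),
                         item_quality = "high",
                         beta_shape = c(1, 1),
                         lambda = rep(1.5, ncol(q)),
                         beta = seq(-1, 1, length.out = ncol(q)),
                         pi = rep(0.5, ncol(q)),
                         seed = NULL) {
  model <- match_model(model)
  q <- as_qmatrix(q)
  K <- ncol(q)
  I <- nrow(q)
  iq <- item_quality_params(item_quality, I)
  if (!is.null(seed)) set.seed(seed)

  truth <- list()
  if (model == "pinc") {
    delta <- simulate_mastery_beta(N, K, beta_shape[1], beta_shape[2])
    person <- delta
    truth$delta <- delta
  } else if (model == "ho-pinc") {
    ho <- simulate_mastery_higher_order(N, lambda, beta)
    person <- ho$delta
    truth$theta <- ho$theta
    truth$delta <- ho$delta
    truth$lambda <- lambda
    truth$beta <- beta
  } else if (model == "dina") {
    alpha <- matrix(rbinom(N * K, 1L, rep(pi, each = N)), N, K)
    person <- alpha
    truth$alpha <- alpha
    truth$pi <- pi
  } else { # ho-dina: theta -> delta -> Bernoulli alpha -> eta
    ho <- simulate_mastery_higher_order(N, lambda, beta)
    alpha <- matrix(rbinom(N * K, 1L, ho$delta), N, K)
    person <- alpha
    truth$theta <- ho$theta
    truth$delta <- ho$delta
    truth$alpha <- alpha
    truth$lambda <- lambda
    truth$beta <- beta
  }

  p <- model_probability_matrix(if (is_probabilistic(model)) "pinc" else "dina",
                                person, iq$slip, iq$guess, q)
  y <- matrix(rbinom(N * I, 1L, p), N, I,
              dimnames = list(paste0("person", seq_len(N)), rownames(q)))

  structure(
    c(list(model = model, y = y, q = q, slip = iq$slip, guess = iq$guess,
           seed = seed, prob = p),
      truth),
    class = "cdm_sim"
  )
}

#' @export
print.cdm_sim <- function(x, ...) {
  cat("Simulated", toupper(x$model), "dataset:",
      nrow(x$y), "persons x", ncol(x$y), "items,",
      ncol(x$q), "attributes\n")
  cat("slip:", format(mean(x$slip), digits = 3),
      " guess:", format(mean(x$guess), digits = 3),
      " (means)\n")
  invisible(x)
}
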