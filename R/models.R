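#' Conjunctive condensation rule
#'
#' Maps a binary latent-variable vector to the ideal (latent) item response:
#' `eta = prod_k x_k^q_k`, with the convention `0^0 = 1` so attributes an item
#' does not require never affect it. Equals 1 iff every required attribute is
#' present.
#'
#' @param x binary latent-variable vector, length K.
#' @param q binary Q-matrix row for the item, length K.
#' @return 0 or 1.
#' @export
conjunctive_condensation <- function(x, q) {
  if (length(x) != length(q)) {
    stop("latent vector and Q-matrix row differ in length", call. = FALSE)
  }
  if (!all(x %in% c(0, 1)) || !all(q %in% c(0, 1))) {
    stop("conjunctive_condensation() expects binary vectors", call. = FALSE)
  }
  as.integer(all(x[q == 1] == 1))
}

#' Probabilistic latent response
#'
#' The probabilistic analogue of the conjunctive rule: given per-attribute
#' mastery probabilities `delta`, the probability that a person holds all the
#' attributes item `i` requires is `rho = prod_k delta_k^q_k` (attributes are
#' conjunctive and independent; `0^0 = 1`).
#'
#' @param delta mastery-probability vector in `[0, 1]`, length K.
#' @param q binary Q-matrix row, length K.
#' @return A probability in `[0, 1]`.
#' @export
probabilistic_latent_response <- function(delta, q) {
  if (length(delta) != length(q)) {
    stop("delta and Q-matrix row differ in length", call. = FALSE)
  }
  if (any(delta < 0 | delta > 1)) {
    stop("mastery probabilities must lie in [0, 1]", call. = FALSE)
  }
  prod(delta[q == 1])
}

# N x I matrix of latent-response probabilities rho (or eta for binary input)
latent_response_matrix <- function(person, q) {
  n <- nrow(person)
  rho <- matrix(1, n, nrow(q))
  for (i in seq_len(nrow(q))) {
    ks <- which(q[i, ] == 1L)
    rho[, i] <- Reduce(`*`, lapply(ks, function(k) person[, k]), rep(1, n))
  }
  rho
}

check_item_params <- function(slip, guess, I = NULL) {
  if (!is.null(I) && (length(slip) != I || length(guess) != I)) {
    stop("slip/guess must have one entry per item", call. = FALSE)
  }
  if (any(slip < 0) || any(guess < 0) || any(guess >= 1 - slip)) {
    stop("item parameters must satisfy s >= 0, g >= 0 and g < 1 - s ",
         "(monotonicity)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Slip-guess response function of the PINC model
#'
#' `p = g + (1 - s - g) * rho`, where `rho` is the probabilistic latent
#' response. The result lies in `[g, 1 - s]`: it equals the guessing
#' probability `g` when no chance of holding all required attributes, and
#' `1 - s` (one minus the slip probability) when mastery is certain.
#'
#' @param delta mastery-probability vector, length K.
#' @param q binary Q-matrix row, length K.
#' @param s,g item slip and guessing probabilities, with `g < 1 - s`.
#' @return The correct-response probability.
#' @export
response_probability_pinc <- function(delta, q, s, g) {
  check_item_params(s, g)
  rho <- probabilistic_latent_response(delta, q)
  g + (1 - s - g) * rho
}

#' Slip-guess response function of the DINA model
#'
#' `p = g + (1 - s - g) * eta` with `eta` from the conjunctive condensation
#' rule. Equals [response_probability_pinc()] evaluated at `delta = alpha`:
#' the DINA model is the PINC model with degenerate (0/1) mastery
#' probabilities.
#'
#' @param alpha binary attribute-profile vector, length K.
#' @inheritParams response_probability_pinc
#' @return The correct-response probability.
#' @export
response_probability_dina <- function(alpha, q, s, g) {
  check_item_params(s, g)
  eta <- conjunctive_condensation(alpha, q)
  g + (1 - s - g) * eta
}

#' Higher-order mastery probability
#'
#' Logistic link from a single higher-order trait to attribute mastery:
#' `delta = plogis(lambda * theta - beta)`. Strictly increasing in `theta`
#' for `lambda > 0`; computed via [stats::plogis()] which is stable for large
#' `|lambda * theta - beta|`.
#'
#' @param theta higher-order latent trait value(s), standard-normal scale.
#' @param lambda attribute slope(s), strictly positive.
#' @param beta attribute intercept(s).
#' @return Mastery probabilities, recycled over the inputs.
#' @export
higher_order_mastery_probability <- function(theta, lambda, beta) {
  if (any(lambda <= 0)) {
    stop("attribute slopes lambda must be strictly positive", call. = FALSE)
  }
  plogis(lambda * theta - beta)
}

#' Bernoulli log-likelihood of a response matrix
#'
#' `sum over observed cells of [Y log p + (1 - Y) log(1 - p)]`. Probabilities
#' are clamped into `[1e-10, 1 - 1e-10]` before logging; `NA` responses
#' contribute nothing.
#'
#' @param y binary response matrix, N x I (`NA` = missing).
#' @param p matrix of correct-response probabilities, same shape.
#' @return The log-likelihood (a scalar).
#' @export
log_likelihood <- function(y, p) {
  y <- as.matrix(y)
  p <- as.matrix(p)
  if (!all(dim(y) == dim(p))) {
    stop("response and probability matrices differ in shape", call. = FALSE)
  }
  eps <- 1e-10
  p <- pmin(pmax(p, eps), 1 - eps)
  obs <- !is.na(y)
  sum(y[obs] * log(p[obs]) + (1 - y[obs]) * log1p(-p[obs]))
}

#' Model probability matrix
#'
#' Dispatches over the four model variants to produce the N x I matrix of
#' correct-response probabilities. For `"pinc"` the person parameters are the
#' N x K mastery-probability matrix `delta`; for `"dina"` the binary N x K
#' profile matrix `alpha`; for the higher-order variants a list with elements
#' `theta` (length N), `lambda` and `beta` (length K), first mapped to `delta`
#' through the logistic link. For `"ho-dina"` the returned entries are the
#' response probabilities conditional on `theta`, marginal over the Bernoulli
#' attribute draws (independent attributes given `theta` make the marginal
#' latent-response probability `prod_k delta_k^q_k`, the same algebra as the
#' probabilistic rule).
#'
#' @param model one of `"pinc"`, `"ho-pinc"`, `"dina"`, `"ho-dina"`.
#' @param person_params matrix or list as described above.
#' @param slip,guess per-item slip and guessing vectors with `g < 1 - s`.
#' @param q Q-matrix.
#' @return An N x I matrix with every entry in `[g_i, 1 - s_i]`.
#' @export
model_probability_matrix <- function(model, person_params, slip, guess, q) {
  model <- match_model(model)
  q <- as_qmatrix(q)
  check_item_params(slip, guess, nrow(q))
  if (is_higher_order(model)) {
    if (!is.list(person_params) ||
        !all(c("theta", "lambda", "beta") %in% names(person_params))) {
      stop("higher-order models need person_params = list(theta, lambda, beta)",
           call. = FALSE)
    }
    delta <- outer_delta(person_params$theta, person_params$lambda,
                         person_params$beta)
  } else {
    delta <- as.matrix(person_params)
    if (ncol(delta) != ncol(q)) {
      stop("person parameters have ", ncol(delta),
           " columns but the Q-matrix has ", ncol(q), " attributes",
           call. = FALSE)
    }
    if (model == "dina" && !all(delta %in% c(0, 1))) {
      stop("the DINA model takes a binary attribute-profile matrix",
           call. = FALSE)
    }
    if (any(delta < 0 | delta > 1)) {
      stop("mastery probabilities must lie in [0, 1]", call. = FALSE)
    }
  }
  rho <- latent_response_matrix(delta, q)
  sweep(rho, 2, 1 - slip - guess, `*`) + rep(guess, each = nrow(rho))
}

# theta (N) x (lambda, beta) (K) -> N x K mastery-probability matrix
outer_delta <- function(theta, lambda, beta) {
  if (length(lambda) != length(beta)) {
    stop("lambda and beta differ in length", call. = FALSE)
  }
  if (any(lambda <= 0)) {
    stop("attribute slopes lambda must be strictly positive", call. = FALSE)
  }
  plogis(outer(theta, lambda) - rep(beta, each = length(theta)))
}
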