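#' Validate a Q-matrix
#'
#' A Q-matrix is the I x K binary design matrix of a diagnostic test:
#' `q[i, k] = 1` means item `i` requires attribute `k`. Items measuring no
#' attribute are rejected; an attribute measured by no item is allowed with a
#' warning (its mastery parameter is unidentified and the posterior returns
#' the prior).
#'
#' @param q matrix or data frame of 0/1 entries, items in rows.
#' @return The validated Q-matrix as a base integer matrix with item and
#'   attribute dimnames.
#' @export
as_qmatrix <- function(q) {
  q <- as.matrix(q)
  storage.mode(q) <- "integer"
  if (anyNA(q) || !all(q %in% c(0L, 1L))) {
    stop("Q-matrix entries must all be 0 or 1", call. = FALSE)
  }
  if (any(rowSums(q) == 0L)) {
    stop("Q-matrix rows ", paste(which(rowSums(q) == 0L), collapse = ", "),
         " measure no attribute", call. = FALSE)
  }
  if (any(colSums(q) == 0L)) {
    warning("Q-matrix attribute column(s) ",
            paste(which(colSums(q) == 0L), collapse = ", "),
            " are measured by no item; the corresponding mastery parameters ",
            "are unidentified", call. = FALSE)
  }
  if (is.null(rownames(q))) rownames(q) <- paste0("item", seq_len(nrow(q)))
  if (is.null(colnames(q))) colnames(q) <- paste0("attr", seq_len(ncol(q)))
  q
}

#' Validate a binary response matrix
#'
#' @param y matrix or data frame of 0/1 item responses, persons in rows.
#'   `NA` marks a missing response; missing cells are dropped from all
#'   likelihood computations.
#' @param q optional Q-matrix; when supplied, `ncol(y)` must equal `nrow(q)`.
#' @return An integer matrix with `NA` for missing entries.
#' @export
as_response_matrix <- function(y, q = NULL) {
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  obs <- y[!is.na(y)]
  if (!all(obs %in% c(0L, 1L))) {
    stop("observed responses must all be 0 or 1", call. = FALSE)
  }
  if (!is.null(q) && ncol(y) != nrow(q)) {
    stop("response matrix has ", ncol(y), " items but the Q-matrix has ",
         nrow(q), call. = FALSE)
  }
  if (is.null(rownames(y))) rownames(y) <- paste0("person", seq_len(nrow(y)))
  y
}

#' Default simulation Q-matrix (5 attributes, 15 or 30 items)
#'
#' Builds the five-attribute design used throughout the simulation studies:
#' items 1-5 each measure a single attribute (identity block), items 6-10
#' measure the adjacent attribute pairs (1,2), (2,3), (3,4), (4,5), (5,1), and
#' items 11-15 measure the sets (1,2,3), (2,3,4), (3,4,5), (1,2,3,4) and all
#' five attributes. With `I = 30` items 16-30 repeat items 1-15.
#'
#' @param I test length, 15 or 30.
#' @param K attribute count; must be 5 for this design (use
#'   [random_qmatrix()] for other sizes).
#' @return An I x 5 Q-matrix.
#' @export
default_qmatrix <- function(I = 15, K = 5) {
  if (!I %in% c(15L, 30L) || K != 5L) {
    stop("default_qmatrix() supports I in {15, 30} with K = 5; ",
         "use random_qmatrix() for other designs", call. = FALSE)
  }
  sets <- c(
    lapply(1:5, identity),                                  # single attribute
    list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1)),      # adjacent pairs
    list(1:3, 2:4, 3:5, 1:4, 1:5)                           # three or more
  )
  q <- matrix(0L, 15L, 5L)
  for (i in seq_along(sets)) q[i, sets[[i]]] <- 1L
  if (I == 30L) q <- rbind(q, q)
  dimnames(q) <- list(paste0("item", seq_len(I)), paste0("attr", 1:5))
  as_qmatrix(q)
}

#' Random Q-matrix generator
#'
#' Draws a required-attribute count for each item from `complexity_weights`,
#' then a uniform attribute subset of that size. Regenerates (up to
#' `max_tries` times) until every attribute is measured by at least one item.
#'
#' @param I,K item and attribute counts.
#' @param complexity_weights named numeric vector of weights over
#'   required-attribute counts; names are the counts. Default weights 1-3
#'   attributes equally.
#' @param seed optional integer seed.
#' @param max_tries attempts before giving up on full attribute coverage.
#' @return An I x K Q-matrix.
#' @export
random_qmatrix <- function(I, K, complexity_weights = NULL, seed = NULL,
                           max_tries = 100L) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(complexity_weights)) {
    complexity_weights <- stats::setNames(rep(1, min(3L, K)),
                                          seq_len(min(3L, K)))
  }
  counts <- as.integer(names(complexity_weights))
  if (anyNA(counts) || any(counts < 1L) || any(counts > K)) {
    stop("complexity_weights names must be counts in 1..K", call. = FALSE)
  }
  for (try in seq_len(max_tries)) {
    sizes <- sample(counts, I, replace = TRUE, prob = complexity_weights)
    q <- matrix(0L, I, K)
    for (i in seq_len(I)) q[i, sample.int(K, sizes[i])] <- 1L
    if (all(colSums(q) > 0L)) {
      dimnames(q) <- list(paste0("item", seq_len(I)), paste0("attr", seq_len(K)))
      return(as_qmatrix(q))
    }
  }
  stop("could not cover every attribute in ", max_tries,
       " tries; adjust complexity_weights or I", call. = FALSE)
}
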