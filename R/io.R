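#' Read and write response and Q-matrices as CSV
#'
#' Comma-separated, UTF-8, header row. Responses: persons as rows, one column
#' per item, missing responses as empty cells. Q-matrices: items as rows, one
#' column per attribute. Write-then-read round-trips the matrices exactly.
#'
#' @param y,q matrices to write.
#' @param path file path.
#' @return The matrix (readers) or the path, invisibly (writers).
#' @name cdm_csv
NULL

#' @rdname cdm_csv
#' @export
write_response_matrix <- function(y, path) {
  y <- as_response_matrix(y)
  utils::write.csv(as.data.frame(y), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname cdm_csv
#' @export
read_response_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  as_response_matrix(as.matrix(df))
}

#' @rdname cdm_csv
#' @export
write_qmatrix <- function(q, path) {
  q <- as_qmatrix(q)
  utils::write.csv(as.data.frame(q), path, row.names = FALSE)
  invisible(path)
}

#' @rdname cdm_csv
#' @export
read_qmatrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  as_qmatrix(as.matrix(df))
}

#' Write a simulated dataset to a directory
#'
#' Emits `Y.csv` (responses), `Q.csv` (design), `truth.json` (generating
#' parameters) and `manifest.json` (model, seed, dimensions, package version,
#' config hash); re-running the simulation from the manifest reproduces the
#' files byte for byte.
#'
#' @param sim a [simulate_cdm()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cdm_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "cdm_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_response_matrix(sim$y, file.path(dir, "Y.csv"))
  write_qmatrix(sim$q, file.path(dir, "Q.csv"))
  truth <- sim[intersect(c("delta", "theta", "alpha", "lambda", "beta", "pi",
                           "slip", "guess"), names(sim))]
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = FALSE)
  manifest <- list(
    kind = "cdm_sim", model = sim$model, seed = sim$seed,
    N = nrow(sim$y), I = ncol(sim$y), K = ncol(sim$q),
    package_version = as.character(utils::packageVersion("pincdm")),
    config_hash = rlang::hash(list(sim$model, sim$seed, dim(sim$y),
                                   sim$slip, sim$guess)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Persist posterior draws to a directory of CSV files
#'
#' One CSV per parameter block and chain (`<block>_chain<c>.csv`, one row per
#' retained draw) plus a JSON manifest recording the model, configuration,
#' seeds and acceptance rates.
#'
#' @param fit a [fit_cdm()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cdm_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "cdm_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in seq_along(fit$chains)) {
    for (b in draw_blocks(fit)) {
      d <- fit$chains[[ch]][[b]]
      if (is.null(d) || (is.matrix(d) && ncol(d) == 0)) next
      utils::write.csv(as.data.frame(as.matrix(d)),
                       file.path(dir, paste0(b, "_chain", ch, ".csv")),
                       row.names = FALSE)
    }
  }
  manifest <- list(
    kind = "cdm_fit", model = fit$model,
    N = fit$N, I = fit$I, K = fit$K,
    control = unclass(fit$control), seed = fit$seed,
    chain_seeds = fit$chain_seeds,
    acceptance = lapply(fit$chains, function(c) as.list(c$acceptance)),
    package_version = as.character(utils::packageVersion("pincdm")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
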