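#' Tidy a fitted diagnosis model
#'
#' One row per monitored scalar with its EAP estimate, posterior standard
#' deviation and (with >= 2 chains) the Brooks-Gelman PSRF. Person-level rows
#' carry `person` / `attribute` indices; item rows carry `item`.
#'
#' @param x a [fit_cdm()] result.
#' @param ... unused.
#' @return A tibble with columns `term`, `block`, `person`, `item`,
#'   `attribute`, `estimate`, `std.error`, `psrf`.
#' @export
tidy.cdm_fit <- function(x, ...) {
  est <- eap_estimates(x)
  est$psrf <- NA_real_
  if (x$control$n_chains >= 2) {
    for (b in unique(est$block)) {
      est$psrf[est$block == b] <- block_psrf(x, b)
    }
  }
  est |>
    dplyr::mutate(
      person = dplyr::if_else(.data$block %in% c("delta", "alpha"),
                              (.data$index - 1L) %% x$N + 1L,
                              dplyr::if_else(.data$block == "theta",
                                             .data$index, NA_integer_)),
      attribute = dplyr::case_when(
        .data$block %in% c("delta", "alpha") ~ (.data$index - 1L) %/% x$N + 1L,
        .data$block %in% c("lambda", "beta", "pi") ~ .data$index,
        TRUE ~ NA_integer_),
      item = dplyr::if_else(.data$block %in% c("s", "g"), .data$index,
                            NA_integer_),
      term = dplyr::case_when(
        .data$block %in% c("delta", "alpha") ~
          paste0(.data$block, "[", .data$person, ",", .data$attribute, "]"),
        .data$block == "theta" ~ paste0("theta[", .data$person, "]"),
        .data$block %in% c("lambda", "beta", "pi") ~
          paste0(.data$block, "[", .data$attribute, "]"),
        TRUE ~ paste0(.data$block, "[", .data$item, "]"))) |>
    dplyr::select("term", "block", "person", "item", "attribute",
                  estimate = "mean", std.error = "sd", "psrf")
}

#' One-row summary of a fitted diagnosis model
#'
#' @param x a [fit_cdm()] result.
#' @param ... unused.
#' @return A tibble with the model tag, data dimensions, draw counts,
#'   posterior mean deviance, `p_D = var(D)/2`, DIC and the maximum PSRF over
#'   monitored parameters.
#' @export
glance.cdm_fit <- function(x, ...) {
  d <- dic(as.numeric(pooled_draws(x, "deviance")))
  max_psrf <- if (x$control$n_chains >= 2) {
    max(convergence_report(x)$psrf)
  } else {
    NA_real_
  }
  tibble::tibble(model = x$model, N = x$N, I = x$I, K = x$K,
                 n_chains = x$control$n_chains,
                 n_draws = x$control$n_chains * n_retained(x),
                 deviance_mean = d$deviance_mean, p_d = d$p_d, dic = d$dic,
                 max_psrf = max_psrf)
}

#' Trace and diagnostic plots for a fitted model
#'
#' @param object a [fit_cdm()] result.
#' @param pars parameter blocks to display (default the item parameters and
#'   deviance; person-level blocks are subsampled to `max_traces` scalars).
#' @param max_traces cap on traces per block.
#' @param ... unused.
#' @return A ggplot of retained-draw traces, one facet per scalar, coloured
#'   by chain.
#' @export
autoplot.cdm_fit <- function(object, pars = NULL, max_traces = 6, ...) {
  if (is.null(pars)) {
    pars <- intersect(c("s", "g", "deviance"), draw_blocks(object))
  }
  df <- purrr::map_dfr(pars, function(b) {
    purrr::map_dfr(seq_along(object$chains), function(ch) {
      d <- chain_draws(object, b, ch)
      keep <- seq_len(min(ncol(d), max_traces))
      purrr::map_dfr(keep, function(j) {
        tibble::tibble(block = b,
                       term = if (ncol(d) > 1) paste0(b, "[", j, "]") else b,
                       chain = factor(ch), iteration = seq_len(nrow(d)),
                       value = d[, j])
      })
    })
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value,
                                   colour = .data$chain)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "retained iteration", y = NULL,
                  title = paste("Posterior traces:", toupper(object$model))) +
    ggplot2::theme_minimal()
}

#' Recovery-report plot
#'
#' Pooled RMSE of the mastery probabilities per attribute (and the
#' higher-order trait where present), with per-item slip/guess RMSE alongside.
#'
#' @param object a [recovery_condition()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.recovery_report <- function(object, ...) {
  df <- object$results |>
    dplyr::filter(.data$statistic == "rmse", .data$aggregation == "pooled")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$index), y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "index (attribute / item)", y = "RMSE",
                  title = sprintf("Parameter recovery: %s, IQ %s, N=%d, I=%d",
                                  toupper(object$condition$model),
                                  object$condition$item_quality,
                                  object$condition$N, object$condition$I)) +
    ggplot2::theme_minimal()
}

#' Q-matrix heatmap
#'
#' @param q a Q-matrix.
#' @return A ggplot tile map (filled = required attribute).
#' @export
plot_qmatrix <- function(q) {
  q <- as_qmatrix(q)
  df <- tidyr::expand_grid(item = seq_len(nrow(q)), attribute = seq_len(ncol(q)))
  df$required <- factor(q[cbind(df$item, df$attribute)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$attribute, y = .data$item,
                                   fill = .data$required)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "grey40")) +
    ggplot2::scale_y_reverse(breaks = seq_len(nrow(q))) +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(q)), position = "top") +
    ggplot2::labs(x = "attribute", y = "item") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
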