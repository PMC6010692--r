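#' Root mean square error
#'
#' @param truth,estimate equal-length numeric vectors.
#' @return `sqrt(mean((estimate - truth)^2))`.
#' @export
rmse <- function(truth, estimate) {
  if (length(truth) != length(estimate) || length(truth) < 1) {
    stop("rmse() needs two equal-length, non-empty vectors", call. = FALSE)
  }
  sqrt(mean((as.numeric(estimate) - as.numeric(truth))^2))
}

#' Pearson correlation between generated and estimated values
#'
#' Thin wrapper over [stats::cor()] that returns `NA` with a warning when
#' either vector is constant (the correlation is undefined).
#'
#' @inheritParams rmse
#' @return The Pearson correlation, or `NA`.
#' @export
pearson_cor <- function(truth, estimate) {
  if (length(truth) != length(estimate) || length(truth) < 2) {
    stop("pearson_cor() needs two equal-length vectors of length >= 2",
         call. = FALSE)
  }
  if (sd(truth) == 0 || sd(estimate) == 0) {
    warning("correlation undefined for a constant vector; returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(truth, estimate)
}

#' One cell of the parameter-recovery design
#'
#' Runs `replications` independent simulate-fit-score cycles for one study
#' condition: data are simulated under the stated model and design, the same
#' (generating) model is fitted by MCMC, convergence is checked over all
#' monitored parameters at `psrf_threshold`, and non-convergent datasets are
#' replaced by freshly simulated ones (with a new derived seed) rather than
#' re-run with longer chains. Scoring follows the recovery-study conventions:
#' per-attribute RMSE and correlation between the generating and EAP
#' mastery values, higher-order trait RMSE/correlation for the HO variants,
#' and per-item slip/guess RMSE. RMSE is reported both pooled over persons
#' and replications and as the mean of per-replication RMSEs; the correlation
#' is reported per replication then averaged, and pooled.
#'
#' @param model model tag; the fitted model always matches the generating one.
#' @param N,I sample size and test length (I in 15/30 uses
#'   [default_qmatrix()]).
#' @param item_quality `"high"` (s = g = 0.1) or `"low"` (s = g = 0.2).
#' @param replications number of replications (the reference protocol uses
#'   30; desk-scale runs use 5).
#' @param control MCMC configuration; see [cdm_mcmc_control()].
#' @param base_seed base seed; replication r, attempt a runs under
#'   [child_seed()]`(base_seed, condition_id * 10^6 + r * 100 + a)`.
#' @param condition_id integer tag separating seed streams across grid cells.
#' @param psrf_threshold convergence gate for dataset replacement.
#' @param max_attempts replacement attempts per replication before erroring.
#' @param q optional explicit Q-matrix overriding the default design.
#' @return A `recovery_report` list: `results` (long tibble of RMSE/Cor by
#'   parameter, index and aggregation), `per_rep` (per-replication scores),
#'   `replaced` (datasets replaced for non-convergence), and the condition.
#' @export
recovery_condition <- function(model, N = 500, I = 15, item_quality = "high",
                               replications = 5,
                               control = cdm_mcmc_control(n_iter = 3000,
                                                          n_burn = 1500),
                               base_seed = 1, condition_id = 0,
                               psrf_threshold = 1.2, max_attempts = 10,
                               q = NULL) {
  model <- match_model(model)
  if (is.null(q)) q <- default_qmatrix(I)
  q <- as_qmatrix(q)
  stopifnot(replications >= 1)

  replaced <- 0L
  per_rep <- list()
  pooled_person <- list()  # per rep: list(truth = N x K, est = N x K)
  pooled_theta <- list()
  item_est <- list()

  truth_block <- function(sim) {
    if (is_probabilistic(model)) sim$delta else sim$alpha
  }

  for (r in seq_len(replications)) {
    fit <- NULL
    for (attempt in 0:(max_attempts - 1)) {
      seed_r <- child_seed(base_seed, condition_id * 1e6 + r * 100 + attempt)
      sim <- simulate_cdm(model, N, q, item_quality, seed = seed_r)
      f <- fit_cdm(sim$y, q, model, control = control,
                   seed = child_seed(seed_r, 7))
      if (converged(f, psrf_threshold)) {
        fit <- f
        break
      }
      replaced <- replaced + 1L
    }
    if (is.null(fit)) {
      stop("replication ", r, " failed to converge (PSRF >= ", psrf_threshold,
           ") in ", max_attempts, " attempts; condition: ", model, " N=", N,
           " I=", I, " IQ=", item_quality, call. = FALSE)
    }

    truth <- truth_block(sim)
    est <- eap_matrix(fit, person_block(fit))
    pooled_person[[r]] <- list(truth = truth, est = est)
    K <- ncol(q)
    rep_rows <- purrr::map_dfr(seq_len(K), function(k) {
      tibble::tibble(replication = r, parameter = "delta", index = k,
                     rmse = rmse(truth[, k], est[, k]),
                     cor = pearson_cor(truth[, k], est[, k]))
    })
    if (is_higher_order(model)) {
      est_theta <- eap_matrix(fit, "theta")
      pooled_theta[[r]] <- list(truth = sim$theta, est = est_theta)
      rep_rows <- dplyr::bind_rows(rep_rows, tibble::tibble(
        replication = r, parameter = "theta", index = 1L,
        rmse = rmse(sim$theta, est_theta),
        cor = pearson_cor(sim$theta, est_theta)))
    }
    per_rep[[r]] <- rep_rows
    item_est[[r]] <- tibble::tibble(
      replication = r, item = seq_len(nrow(q)),
      s_true = sim$slip, s_est = eap_matrix(fit, "s"),
      g_true = sim$guess, g_est = eap_matrix(fit, "g"))
  }

  per_rep <- dplyr::bind_rows(per_rep)
  items <- dplyr::bind_rows(item_est)

  # person-parameter summaries: pooled over persons x replications, and
  # replication means
  K <- ncol(q)
  person_rows <- purrr::map_dfr(seq_len(K), function(k) {
    tr <- unlist(lapply(pooled_person, function(x) x$truth[, k]))
    es <- unlist(lapply(pooled_person, function(x) x$est[, k]))
    reps_k <- dplyr::filter(per_rep, .data$parameter == "delta",
                            .data$index == k)
    tibble::tibble(
      parameter = "delta", index = k,
      statistic = rep(c("rmse", "cor"), each = 2),
      aggregation = rep(c("pooled", "rep_mean"), 2),
      value = c(rmse(tr, es), mean(reps_k$rmse),
                pearson_cor(tr, es), mean(reps_k$cor)))
  })
  if (is_higher_order(model)) {
    tr <- unlist(lapply(pooled_theta, function(x) x$truth))
    es <- unlist(lapply(pooled_theta, function(x) x$est))
    reps_t <- dplyr::filter(per_rep, .data$parameter == "theta")
    person_rows <- dplyr::bind_rows(person_rows, tibble::tibble(
      parameter = "theta", index = 1L,
      statistic = rep(c("rmse", "cor"), each = 2),
      aggregation = rep(c("pooled", "rep_mean"), 2),
      value = c(rmse(tr, es), mean(reps_t$rmse),
                pearson_cor(tr, es), mean(reps_t$cor))))
  }
  item_rows <- items |>
    dplyr::group_by(.data$item) |>
    dplyr::summarise(
      s = sqrt(mean((.data$s_est - .data$s_true)^2)),
      g = sqrt(mean((.data$g_est - .data$g_true)^2)),
      .groups = "drop") |>
    tidyr::pivot_longer(c("s", "g"), names_to = "parameter",
                        values_to = "value") |>
    dplyr::transmute(parameter = .data$parameter, index = .data$item,
                     statistic = "rmse", aggregation = "pooled",
                     value = .data$value)

  results <- dplyr::bind_rows(person_rows, item_rows) |>
    dplyr::mutate(model = model, item_quality = item_quality, N = N, I = I,
                  .before = 1)

  structure(list(results = results, per_rep = per_rep, items = items,
                 replaced = replaced,
                 condition = list(model = model, N = N, I = I,
                                  item_quality = item_quality,
                                  replications = replications,
                                  base_seed = base_seed,
                                  condition_id = condition_id,
                                  control = control,
                                  psrf_threshold = psrf_threshold)),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cond <- x$condition
  cat("Recovery study:", toupper(cond$model), "| IQ", cond$item_quality,
      "| N =", cond$N, "| I =", cond$I, "|", cond$replications,
      "replications (", x$replaced, "datasets replaced )\n")
  wide <- x$results |>
    dplyr::filter(.data$parameter %in% c("delta", "theta"),
                  .data$aggregation == ifelse(.data$statistic == "rmse",
                                              "pooled", "rep_mean")) |>
    tidyr::pivot_wider(id_cols = c("parameter", "index"),
                       names_from = "statistic", values_from = "value")
  print(wide, n = Inf)
  invisible(x)
}

#' Extract the long results table from recovery output
#'
#' @param report a `recovery_report` or `recovery_grid` object.
#' @return The long tibble of RMSE / correlation values.
#' @export
recovery_results <- function(report) {
  if (inherits(report, "recovery_report")) return(report$results)
  if (inherits(report, "recovery_grid")) return(report$results)
  stop("not a recovery report", call. = FALSE)
}

#' Build a study condition grid
#'
#' Crosses the design factors of the recovery study (sample size, test
#' length, item quality) for one or more models into a tibble of conditions,
#' one row per cell.
#'
#' @param model model tag(s).
#' @param N,I,item_quality design factor levels.
#' @param replications replications per cell.
#' @return A tibble with one condition per row and a `condition_id` column.
#' @export
condition_grid <- function(model = "pinc", N = c(500, 1000), I = c(15, 30),
                           item_quality = c("high", "low"),
                           replications = 5) {
  g <- tidyr::expand_grid(model = model, item_quality = item_quality,
                          N = N, I = I)
  g$replications <- replications
  g$condition_id <- seq_len(nrow(g))
  g
}

#' Run a grid of recovery conditions
#'
#' Runs [recovery_condition()] for every row of a condition grid under
#' deterministic derived seeds. A failing condition is collected as an error
#' message, not fatal to its siblings.
#'
#' @param conditions a tibble from [condition_grid()].
#' @param control MCMC configuration applied to every cell.
#' @param base_seed base seed for the whole study.
#' @param ... passed to [recovery_condition()].
#' @return A `recovery_grid` list with the combined long `results` tibble,
#'   the per-condition reports, and any `failures`.
#' @export
run_recovery_grid <- function(conditions,
                              control = cdm_mcmc_control(n_iter = 3000,
                                                         n_burn = 1500),
                              base_seed = 1, ...) {
  stopifnot(nrow(conditions) >= 1)
  reports <- vector("list", nrow(conditions))
  failures <- list()
  for (j in seq_len(nrow(conditions))) {
    row <- conditions[j, ]
    reports[[j]] <- tryCatch(
      recovery_condition(row$model, N = row$N, I = row$I,
                         item_quality = row$item_quality,
                         replications = row$replications,
                         control = control, base_seed = base_seed,
                         condition_id = row$condition_id, ...),
      error = function(e) e)
    if (inherits(reports[[j]], "error")) {
      failures[[length(failures) + 1]] <- list(condition = row,
                                               message = conditionMessage(reports[[j]]))
      reports[[j]] <- NULL
    }
  }
  ok <- !vapply(reports, is.null, logical(1))
  results <- dplyr::bind_rows(lapply(reports[ok], recovery_results))
  structure(list(results = results, reports = reports[ok],
                 failures = failures, conditions = conditions,
                 base_seed = base_seed),
            class = "recovery_grid")
}

#' @export
print.recovery_grid <- function(x, ...) {
  cat("Recovery grid:", nrow(x$conditions), "conditions,",
      length(x$failures), "failures\n")
  print(dplyr::filter(x$results, .data$parameter %in% c("delta", "theta")),
        n = 40)
  invisible(x)
}
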