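#' Monte Carlo standard error of a mean
#'
#' Sample standard deviation divided by the square root of the number of
#' replicates; the precision with which a simulation's average estimates the
#' corresponding expectation.
#'
#' @param values Numeric vector of per-replicate values (NAs dropped).
#' @return Scalar Monte Carlo error.
#' @examples
#' mc_error(c(0, 2)) # sd sqrt(2), n 2 -> 1
#' @export
mc_error <- function(values) {
  values <- values[is.finite(values)]
  stats::sd(values) / sqrt(length(values))
}

.method_ids <- c("cl-unadj", "cl-adj", "lmm", "cmi", "mi")

# Run one method on one incomplete dataset, returning a crt_result row.
run_method <- function(method, data, scenario, ci_level, Q, burn_in, thin,
                       mi_seed = NULL) {
  switch(method,
    "cl-unadj" = cl_unadjusted(data, ci_level),
    "cl-adj"   = cl_adjusted(data, ci_level),
    "lmm"      = fit_lmm_cra(data, lmm_spec(interaction = scenario$interaction),
                             ci_level),
    "cmi"      = adjusted_ttest(impute_cluster_mean(data), ci_level),
    "mi"       = mi_analyze(
                   mi_impute(data, Q = Q, burn_in = burn_in, thin = thin,
                             interaction = scenario$interaction, seed = mi_seed),
                   ci_level),
    stop("unknown method id: ", method, call. = FALSE)
  )
}

#' Run one cell of the simulation experiment
#'
#' For each replicate: generate complete data under the scenario, impose its
#' missingness mechanism, and run every requested method on the same
#' incomplete dataset. A master seed spawns independent sub-seeds per
#' replicate and per stage (outcome draw, missingness draw, imputation
#' draw), so adding or removing methods never perturbs the generated data.
#'
#' Methods: `"cl-unadj"` (unadjusted cluster-level), `"cl-adj"`
#' (covariate-adjusted cluster-level), `"lmm"` (complete-records REML mixed
#' model, interaction per scenario), `"cmi"` (cluster-mean imputation
#' followed by the adjusted t-test), `"mi"` (random-effects multiple
#' imputation analysed by LMM, Rubin/Barnard-Rubin pooling).
#'
#' Replicates where a method fails to converge are excluded from that
#' method's averages and counted in `n_failures`.
#'
#' @param scenario A [make_scenario()] object.
#' @param methods Character vector of method ids.
#' @param n_reps Number of replicates.
#' @param seed Master seed.
#' @param ci_level Confidence level for coverage.
#' @param Q,burn_in,thin Multiple-imputation settings (defaults 20, 200, 10).
#' @param keep_estimates Also return the per-replicate estimates?
#' @return A tibble of class `crt_sim_summary`, one row per method:
#'   `scenario`, `k`, `rho`, `method_id`, `n_reps`, `avg_estimate`,
#'   `empirical_sd`, `avg_se`, `coverage`, `mc_error_estimate`,
#'   `mc_error_se`, `avg_nu_adj` (MI only, else NA), `n_failures`,
#'   `true_effect`. With `keep_estimates = TRUE` the per-replicate estimate
#'   matrix is attached as attribute `estimates`.
#' @examples
#' run_cell(make_scenario(1, k = 5), methods = "cl-unadj", n_reps = 20, seed = 1)
#' @export
run_cell <- function(scenario, methods = c("cl-unadj", "cl-adj", "lmm"),
                     n_reps = 2000, seed = NULL, ci_level = 0.95,
                     Q = 20, burn_in = 200, thin = 10,
                     keep_estimates = FALSE) {
  stopifnot(inherits(scenario, "crt_scenario"), n_reps >= 1)
  stopifnot(all(methods %in% .method_ids))
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 3 * n_reps), ncol = 3)
  true_effect <- scenario$true_effect
  per_rep <- purrr::map(seq_len(n_reps), function(rep) {
    d <- generate_complete(scenario$design, scenario$outcome,
                           seed = sub_seeds[rep, 1])
    d <- impose_missingness(d, scenario$missingness, seed = sub_seeds[rep, 2])
    purrr::map(methods, function(mth) {
      res <- tryCatch(
        run_method(mth, d, scenario, ci_level, Q, burn_in, thin,
                   mi_seed = sub_seeds[rep, 3]),
        error = function(e) NULL)
      if (is.null(res)) {
        res <- tibble::tibble(method_id = mth, estimate = NA_real_,
                              se = NA_real_, df = NA_real_, ci_low = NA_real_,
                              ci_high = NA_real_, p_value = NA_real_,
                              warnings = list("failed"))
      }
      nu_adj <- if (mth == "mi" && !is.null(attr(res, "pooled")))
        attr(res, "pooled")$nu_adj else NA_real_
      failed <- !is.finite(res$estimate) ||
        "nonconvergence" %in% res$warnings[[1]] || "failed" %in% res$warnings[[1]]
      tibble::tibble(rep = rep, method_id = mth, estimate = res$estimate,
                     se = res$se, ci_low = res$ci_low, ci_high = res$ci_high,
                     nu_adj = nu_adj, failed = failed)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  summ <- per_rep |>
    dplyr::group_by(.data$method_id) |>
    dplyr::summarise(
      n_reps = dplyr::n(),
      n_failures = sum(.data$failed),
      avg_estimate = mean(.data$estimate[!.data$failed]),
      empirical_sd = stats::sd(.data$estimate[!.data$failed]),
      avg_se = mean(.data$se[!.data$failed]),
      coverage = mean((.data$ci_low <= true_effect &
                         .data$ci_high >= true_effect)[!.data$failed]),
      mc_error_estimate = mc_error(.data$estimate[!.data$failed]),
      mc_error_se = mc_error(.data$se[!.data$failed]),
      avg_nu_adj = mean(.data$nu_adj[!.data$failed]),
      .groups = "drop") |>
    dplyr::mutate(scenario = .env$scenario$id, k = .env$scenario$design$k[1],
                  rho = .env$scenario$outcome$rho, true_effect = true_effect,
                  method_id = factor(.data$method_id, levels = .method_ids)) |>
    dplyr::arrange(.data$method_id) |>
    dplyr::mutate(method_id = as.character(.data$method_id)) |>
    dplyr::relocate("scenario", "k", "rho", "method_id")
  if (any(summ$n_failures > 0.01 * summ$n_reps)) {
    warning("a method failed on more than 1% of replicates", call. = FALSE)
  }
  class(summ) <- c("crt_sim_summary", class(summ))
  if (keep_estimates) attr(summ, "estimates") <- per_rep
  summ
}

#' Run a factorial table of simulation cells
#'
#' Crosses a scenario with grids of clusters-per-arm and intraclass
#' correlation, running [run_cell()] in each cell; the canonical experiment
#' uses `k` in (5, 10, 20, 30) and `rho` in (0.001, 0.05, 0.1).
#'
#' @param scenario_id Scenario 1-4.
#' @param methods Method ids as in [run_cell()].
#' @param k_grid,rho_grid Design grids.
#' @param n_reps Replicates per cell.
#' @param seed Master seed (per-cell seeds are spawned from it).
#' @param ... Passed to [run_cell()] (e.g. `Q`, `burn_in`, `thin`).
#' @return A `crt_sim_summary` tibble, one row per (k, rho, method).
#' @export
run_table <- function(scenario_id, methods = c("cl-unadj", "cl-adj", "lmm"),
                      k_grid = c(5, 10, 20, 30),
                      rho_grid = c(0.001, 0.05, 0.1),
                      n_reps = 2000, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(k = k_grid, rho = rho_grid)
  grid$cell_seed <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  if (!length(methods)) return(tibble::tibble())
  out <- purrr::pmap(grid, function(k, rho, cell_seed) {
    run_cell(make_scenario(scenario_id, k = k, rho = rho), methods = methods,
             n_reps = n_reps, seed = cell_seed, ...)
  }) |> dplyr::bind_rows()
  class(out) <- c("crt_sim_summary", class(out))
  out
}
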