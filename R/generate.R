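#' Generate complete outcome data for a two-arm cluster randomised trial
#'
#' Draws one long-format dataset from the random-intercept outcome model: a
#' standard-normal baseline covariate per individual, a normal cluster effect
#' with variance \eqn{\rho\sigma_y^2} per cluster, and a normal individual
#' error with per-arm variance \eqn{(1-\tau_i^2-\rho)\sigma_y^2}.
#'
#' @param design A [trial_design()].
#' @param outcome An [outcome_params()].
#' @param seed Optional integer seed; when supplied the draw is reproducible.
#' @return A tibble with one row per individual and columns `arm` (1 control,
#'   2 intervention), `cluster` (id, 1-based within arm), `individual`
#'   (1-based within cluster), `x`, `y`, and `r` (observation indicator,
#'   all 1 for complete data).
#' @examples
#' d <- generate_complete(trial_design(10, 30), outcome_params(), seed = 1)
#' dplyr::count(d, arm)
#' @export
generate_complete <- function(design, outcome, seed = NULL) {
  stopifnot(inherits(design, "crt_design"), inherits(outcome, "crt_outcome"))
  if (!is.null(seed)) set.seed(seed)
  arms <- purrr::map(1:2, function(i) {
    sizes <- design$m[[i]]
    k <- design$k[i]
    n <- sum(sizes)
    cl <- rep.int(seq_len(k), sizes)
    x <- stats::rnorm(n)
    delta <- stats::rnorm(k, 0, sqrt(outcome$sigma_b2))
    eps <- stats::rnorm(n, 0, sqrt(outcome$sigma_w2[i]))
    tibble::tibble(
      arm = i,
      cluster = cl,
      individual = sequence(sizes),
      x = x,
      y = outcome$alpha[i] + outcome$beta[i] * x + delta[cl] + eps,
      r = 1L
    )
  })
  dplyr::bind_rows(arms)
}

#' Impose covariate-dependent missingness on a complete dataset
#'
#' Each record's observation indicator is drawn independently with
#' \eqn{P(R = 0) = \mathrm{expit}(\varphi_{i0} + \varphi_{i1} x)} using its
#' arm's parameters. The true outcome values are retained in `y` (masking is
#' flag-based via `r`), so bias diagnostics against the truth remain possible;
#' every analysis function honours `r` and uses `y` only where `r == 1`.
#'
#' @param data A CRT dataset tibble (all records observed).
#' @param miss A [missingness_params()].
#' @param seed Optional integer seed.
#' @return The dataset with `r` set to 0 for records drawn missing.
#' @examples
#' d <- generate_complete(trial_design(10, 30), outcome_params(), seed = 1)
#' dm <- impose_missingness(d, missingness_params(phi0 = -1, phi1 = 1), seed = 2)
#' mean(dm$r == 0)
#' @export
impose_missingness <- function(data, miss, seed = NULL) {
  stopifnot(inherits(miss, "crt_missingness"))
  data <- check_crt_data(data)
  stopifnot(all(data$r == 1))
  if (!is.null(seed)) set.seed(seed)
  p_miss <- stats::plogis(miss$phi0[data$arm] + miss$phi1[data$arm] * data$x)
  dplyr::mutate(data, r = as.integer(stats::runif(dplyr::n()) >= p_miss))
}

#' Solve for the missingness intercept giving a target observed proportion
#'
#' Finds \eqn{\varphi_0} such that the marginal observed proportion
#' \eqn{E_X[\mathrm{expit}(-\varphi_0 - \varphi_1 X)]} equals
#' `target_observed` for `X ~ N(0, 1)`, by root-finding on a quadrature
#' evaluation of the integral. The observed proportion is strictly decreasing
#' in \eqn{\varphi_0}, so the root is unique.
#'
#' @param target_observed Desired marginal probability of observation, in (0, 1).
#' @param phi1 Missingness slope.
#' @return The intercept `phi0` (scalar).
#' @examples
#' calibrate_phi0(0.70, phi1 = 1) # about -1: the 30%-missing arms
#' @export
calibrate_phi0 <- function(target_observed, phi1) {
  stopifnot(target_observed > 0, target_observed < 1, is.finite(phi1))
  f <- function(phi0) prob_observed(phi0, phi1) - target_observed
  lo <- -1; hi <- 1
  while (f(lo) < 0) lo <- lo * 2
  while (f(hi) > 0) hi <- hi * 2
  stopifnot(f(lo) >= 0, f(hi) <= 0)
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Generate an incomplete dataset for a scenario
#'
#' Convenience wrapper: draws complete data and imposes the scenario's
#' missingness mechanism, using separate sub-seeds for the two stages so that
#' the outcome draw is unchanged by changes to the missingness stage.
#'
#' @param scenario A [make_scenario()] object.
#' @param seed Optional integer seed.
#' @return An incomplete CRT dataset tibble.
#' @export
generate_scenario <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "crt_scenario"))
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 2)
  d <- generate_complete(scenario$design, scenario$outcome, seed = seeds[1])
  impose_missingness(d, scenario$missingness, seed = seeds[2])
}

# Validate the long-format record layout; returns the data as a tibble.
check_crt_data <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("arm", "cluster", "individual", "x", "y", "r")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("CRT data must have columns arm, cluster, individual, x, y, r; missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  stopifnot(all(data$arm %in% 1:2), all(data$r %in% 0:1))
  tibble::as_tibble(data)
}

#' Read or write a CRT dataset as CSV
#'
#' The CSV layout is `arm,cluster,individual,x,y,r` with `r` in `{0, 1}`.
#' When writing with `as_observed = TRUE`, outcomes with `r == 0` are written
#' as empty fields (the dataset as an analyst would receive it); otherwise the
#' retained true values are written.
#'
#' @param path File path.
#' @param data Dataset to write.
#' @param as_observed Blank out unobserved outcomes on write?
#' @return `read_crt_csv()` returns the dataset tibble; `write_crt_csv()`
#'   returns `data` invisibly.
#' @export
read_crt_csv <- function(path) {
  df <- utils::read.csv(path)
  check_crt_data(df)
}

#' @rdname read_crt_csv
#' @export
write_crt_csv <- function(data, path, as_observed = FALSE) {
  data <- check_crt_data(data)
  if (as_observed) data$y[data$r == 0] <- NA_real_
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(data)
}
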