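#' Define the design of a two-arm cluster randomised trial
#'
#' A trial design fixes the number of clusters randomised to each arm and the
#' number of individuals per cluster. Arm 1 is the control group, arm 2 the
#' intervention group. Balanced designs (equal `k`, constant `m`) are the
#' common case; per-arm `k` and per-cluster `m` are accepted.
#'
#' @param k Clusters per arm. Length 1 (both arms) or 2 (`c(k1, k2)`). Must be
#'   at least 2 per arm so that a between-cluster variance is estimable.
#' @param m Individuals per cluster. Length 1 (all clusters), or a list of two
#'   integer vectors giving each cluster's size within each arm.
#' @return An object of class `crt_design`: a list with integer vectors
#'   `k` (length 2) and `m` (list of two per-cluster size vectors).
#' @examples
#' trial_design(k = 10, m = 30)
#' @export
trial_design <- function(k = 10, m = 30) {
  if (length(k) == 1) k <- c(k, k)
  stopifnot(length(k) == 2, all(k == round(k)), all(k >= 2))
  k <- as.integer(k)
  if (!is.list(m)) {
    stopifnot(length(m) == 1, m >= 1, m == round(m))
    m <- list(rep(as.integer(m), k[1]), rep(as.integer(m), k[2]))
  }
  stopifnot(length(m) == 2, lengths(m) == k, all(unlist(m) >= 1))
  structure(list(k = k, m = lapply(m, as.integer)), class = "crt_design")
}

#' Parameters of the outcome-generating random-intercept model
#'
#' The outcome for individual l in cluster j of arm i follows
#' \deqn{Y_{ijl} = \alpha_i + \beta_i X_{ijl} + \delta_{ij} + \epsilon_{ijl}}
#' with a standard-normal baseline covariate X, cluster effects
#' \eqn{\delta_{ij} \sim N(0, \rho\sigma_y^2)} and individual errors
#' \eqn{\epsilon_{ijl} \sim N(0, (1-\tau_i^2-\rho)\sigma_y^2)}. Because
#' \eqn{Var(X) = 1}, the covariate effect is parameterised through the
#' outcome-covariate correlation \eqn{\tau_i} as \eqn{\beta_i = \tau_i\sigma_y},
#' which keeps the total within-arm outcome variance at \eqn{\sigma_y^2} and
#' the unconditional intraclass correlation at \eqn{\rho}.
#'
#' @param alpha Per-arm intercepts `c(alpha1, alpha2)` (outcome units).
#' @param tau Per-arm outcome-covariate correlations `c(tau1, tau2)`,
#'   each with absolute value below 1.
#' @param sigma_y2 Total within-arm outcome variance (outcome units squared).
#' @param rho Unconditional intraclass correlation, in `[0, 1)`.
#' @return An object of class `crt_outcome`: a list with `alpha`, `tau`,
#'   `sigma_y2`, `rho` and the derived quantities `beta` (per-arm covariate
#'   effect), `sigma_b2` (between-cluster variance) and `sigma_w2` (per-arm
#'   individual error variance).
#' @examples
#' outcome_params(alpha = c(20, 25), tau = c(0.5, 0.5), sigma_y2 = 100, rho = 0.05)
#' @export
outcome_params <- function(alpha = c(20, 25), tau = c(0.5, 0.5),
                           sigma_y2 = 100, rho = 0.05) {
  if (length(tau) == 1) tau <- c(tau, tau)
  stopifnot(length(alpha) == 2, length(tau) == 2, sigma_y2 > 0,
            rho >= 0, rho < 1, all(abs(tau) < 1))
  sigma_w2 <- (1 - tau^2 - rho) * sigma_y2
  if (any(sigma_w2 <= 0)) {
    stop("invalid variance decomposition: need 1 - tau_i^2 - rho > 0 in both arms",
         call. = FALSE)
  }
  structure(list(alpha = as.numeric(alpha), tau = as.numeric(tau),
                 sigma_y2 = as.numeric(sigma_y2), rho = as.numeric(rho),
                 beta = tau * sqrt(sigma_y2),
                 sigma_b2 = rho * sigma_y2,
                 sigma_w2 = sigma_w2),
            class = "crt_outcome")
}

#' Parameters of the per-arm logistic missingness mechanism
#'
#' Outcomes go missing with probability
#' \deqn{P(R_{ijl} = 0 \mid X_{ijl}) = \mathrm{expit}(\varphi_{i0} + \varphi_{i1} X_{ijl})}
#' independently across individuals, depending only on the fully observed
#' baseline covariate (covariate dependent missingness, a special case of
#' missing at random).
#'
#' @param phi0 Per-arm intercepts on the logit scale (length 1 or 2).
#' @param phi1 Per-arm slopes, logit per covariate unit (length 1 or 2).
#' @return An object of class `crt_missingness`: list with numeric `phi0`,
#'   `phi1`, each length 2.
#' @examples
#' missingness_params(phi0 = -1, phi1 = 1)
#' @export
missingness_params <- function(phi0 = -1, phi1 = 1) {
  if (length(phi0) == 1) phi0 <- c(phi0, phi0)
  if (length(phi1) == 1) phi1 <- c(phi1, phi1)
  stopifnot(length(phi0) == 2, length(phi1) == 2,
            all(is.finite(phi0)), all(is.finite(phi1)))
  structure(list(phi0 = as.numeric(phi0), phi1 = as.numeric(phi1)),
            class = "crt_missingness")
}

# Scenario constants shared by all four study conditions.
.scenario_constants <- list(alpha = c(20, 25), sigma_y2 = 100, m = 30, phi1 = c(1, 1))

.scenario_table <- list(
  `1` = list(phi0 = c(-1, -1),  tau = c(0.5, 0.5), interaction = FALSE),
  `2` = list(phi0 = c(-1, 0.5), tau = c(0.5, 0.5), interaction = FALSE),
  `3` = list(phi0 = c(-1, -1),  tau = c(0.4, 0.6), interaction = TRUE),
  `4` = list(phi0 = c(-1, 0.5), tau = c(0.4, 0.6), interaction = TRUE)
)

#' Build one of the four canonical simulation scenarios
#'
#' The four scenarios cross two factors: whether the missingness mechanism is
#' the same in both arms (scenarios 1, 3: 30% missing in each arm) or differs
#' (scenarios 2, 4: 30% missing in control, 60% in intervention), and whether
#' the covariate effect on outcome is the same (`tau = 0.5` both arms,
#' scenarios 1-2) or differs (`tau = (0.4, 0.6)`, scenarios 3-4, i.e. a
#' covariate-by-intervention interaction in the outcome model). Constants
#' shared by all scenarios: intercepts 20 and 25 (true intervention effect 5),
#' total outcome variance 100, cluster size 30, missingness slope 1.
#'
#' @param id Scenario identifier, 1 to 4.
#' @param k Clusters per arm.
#' @param rho Unconditional intraclass correlation.
#' @return An object of class `crt_scenario`: list with `id`, `design`
#'   (`crt_design`), `outcome` (`crt_outcome`), `missingness`
#'   (`crt_missingness`), `interaction` (logical: does the outcome model have
#'   differing covariate effects, so analysis models should include the
#'   interaction) and `true_effect` (arm 2 minus arm 1).
#' @examples
#' sc <- make_scenario(4, k = 10, rho = 0.05)
#' sc$missingness$phi0
#' @export
make_scenario <- function(id, k = 10, rho = 0.05) {
  if (length(id) != 1 || !id %in% 1:4) {
    stop("unknown scenario id: must be 1, 2, 3 or 4", call. = FALSE)
  }
  cc <- .scenario_constants
  sc <- .scenario_table[[as.character(id)]]
  structure(list(
    id = as.integer(id),
    design = trial_design(k = k, m = cc$m),
    outcome = outcome_params(alpha = cc$alpha, tau = sc$tau,
                             sigma_y2 = cc$sigma_y2, rho = rho),
    missingness = missingness_params(phi0 = sc$phi0, phi1 = cc$phi1),
    interaction = sc$interaction,
    true_effect = cc$alpha[2] - cc$alpha[1]
  ), class = "crt_scenario")
}

#' @export
print.crt_scenario <- function(x, ...) {
  cat("CRT simulation scenario", x$id, "\n")
  cat("  clusters/arm:", paste(x$design$k, collapse = ", "),
      " cluster size:", x$design$m[[1]][1], "\n")
  cat("  alpha:", paste(x$outcome$alpha, collapse = ", "),
      " tau:", paste(x$outcome$tau, collapse = ", "),
      " rho:", x$outcome$rho, "\n")
  cat("  missingness phi0:", paste(x$missingness$phi0, collapse = ", "),
      " phi1:", paste(x$missingness$phi1, collapse = ", "), "\n")
  cat("  interaction in analysis models:", x$interaction, "\n")
  invisible(x)
}
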