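# Marginal probability that an outcome is observed under the logistic
# selection model with X ~ N(0,1): E[expit(-phi0 - phi1 X)].
prob_observed <- function(phi0, phi1) {
  stats::integrate(function(x) stats::plogis(-phi0 - phi1 * x) * stats::dnorm(x),
                   -Inf, Inf, rel.tol = 1e-12, abs.tol = 1e-12)$value
}

#' Moments of the covariate among individuals with observed outcomes
#'
#' Under selection \eqn{P(R=1|X=x) = \mathrm{expit}(-\varphi_0 - \varphi_1 x)}
#' with `X ~ N(0,1)`, the covariate among observed individuals follows the
#' tilted density \eqn{\phi(x)\,\mathrm{expit}(-\varphi_0-\varphi_1 x)/p_{obs}}.
#' This computes, by adaptive quadrature, the observation probability, the
#' mean and variance of X given observation, the effective observed cluster
#' size \eqn{\eta} defined through \eqn{1/\eta = E(1/\sum_l R_{ijl})}
#' (conditional on at least one observed outcome, since clusters with none
#' are dropped by the cluster-level estimators), and the variance
#' \eqn{\sigma^2_{\bar x | obs}} of a cluster's observed-covariate mean.
#'
#' The per-cluster observed count is Binomial(m, p_obs) because covariates are
#' independent across individuals, so \eqn{E(1/n)} is an exact finite sum.
#'
#' @param phi0,phi1 Missingness model intercept and slope for one arm.
#' @param m Cluster size.
#' @return A one-row tibble: `p_obs`, `mu_x_obs`, `var_x_obs`, `eta`,
#'   `sigma2_xbar_obs`.
#' @examples
#' selection_moments(-1, 1, m = 30)
#' @export
selection_moments <- function(phi0, phi1, m = 30) {
  stopifnot(is.finite(phi0), is.finite(phi1), m >= 1)
  p_obs <- prob_observed(phi0, phi1)
  if (p_obs < 1e-12 || p_obs > 1 - 1e-12) {
    stop("observation probability numerically 0 or 1", call. = FALSE)
  }
  tilt <- function(x) stats::plogis(-phi0 - phi1 * x) * stats::dnorm(x) / p_obs
  qint <- function(f) stats::integrate(f, -Inf, Inf,
                                       rel.tol = 1e-12, abs.tol = 1e-10)$value
  mu <- qint(function(x) x * tilt(x))
  ex2 <- qint(function(x) x^2 * tilt(x))
  var_x <- ex2 - mu^2
  n <- seq_len(m)
  # E(1/n_obs | n_obs >= 1); the truncation correction is negligible at the
  # study settings but keeps eta well defined for any p_obs.
  e_inv_n <- sum((1 / n) * stats::dbinom(n, m, p_obs)) / (1 - (1 - p_obs)^m)
  eta <- 1 / e_inv_n
  tibble::tibble(p_obs = p_obs, mu_x_obs = mu, var_x_obs = var_x,
                 eta = eta, sigma2_xbar_obs = var_x / eta)
}

# Per-arm selection moments for a missingness spec.
arm_moments <- function(miss, m) {
  dplyr::bind_rows(
    selection_moments(miss$phi0[1], miss$phi1[1], m),
    selection_moments(miss$phi0[2], miss$phi1[2], m)
  )
}

#' Expected value and bias of the unadjusted cluster-level estimator
#'
#' Under covariate-dependent missingness the complete-records difference of
#' arm means of cluster means has expectation (control-minus-intervention
#' algebra, reported here on the arm2-minus-arm1 scale)
#' \deqn{E(\hat\theta^{obs}) = \mu_2 - \mu_1 + \beta_2\mu_{x21} - \beta_1\mu_{x11}}
#' with \eqn{\mu_{xi1}} the mean covariate among observed individuals in arm
#' i (the population covariate mean is 0). The bias vanishes when
#' \eqn{\beta_1\mu_{x11} = \beta_2\mu_{x21}}, in particular when both arms
#' share the covariate effect and the missingness mechanism.
#'
#' @param outcome An [outcome_params()].
#' @param moments Two-row tibble of per-arm [selection_moments()] (row order:
#'   control, intervention).
#' @return One-row tibble: `expected_estimate`, `bias`, `true_effect`
#'   (all arm2 minus arm1).
#' @export
expected_bias_unadjusted <- function(outcome, moments) {
  stopifnot(inherits(outcome, "crt_outcome"), nrow(moments) == 2)
  true_effect <- outcome$alpha[2] - outcome$alpha[1]
  bias <- outcome$beta[2] * moments$mu_x_obs[2] -
    outcome$beta[1] * moments$mu_x_obs[1]
  tibble::tibble(expected_estimate = true_effect + bias, bias = bias,
                 true_effect = true_effect)
}

#' Variance of the unadjusted cluster-level estimator under missingness
#'
#' \deqn{Var(\hat\theta^{obs}) = \sum_{i=1}^{2} \frac{1}{k_i}\left(
#'   \beta_i^2\sigma^2_{\bar x i 1} + \sigma_b^2 + \sigma_{w,i}^2/\eta_i\right)}
#' where \eqn{1/\eta_i = E(1/n_{obs})} and \eqn{\sigma^2_{\bar x i1}} is the
#' variance of a cluster's mean observed covariate. The individual error
#' variance is taken arm-specific, \eqn{\sigma_{w,i}^2 = (1-\tau_i^2-\rho)\sigma_y^2}.
#'
#' @inheritParams expected_bias_unadjusted
#' @param design A [trial_design()].
#' @return Scalar variance.
#' @export
var_unadjusted <- function(outcome, design, moments) {
  stopifnot(inherits(design, "crt_design"), nrow(moments) == 2)
  per_arm <- outcome$beta^2 * moments$sigma2_xbar_obs + outcome$sigma_b2 +
    outcome$sigma_w2 / moments$eta
  sum(per_arm / design$k)
}

#' Expected value and bias of the covariate-adjusted cluster-level estimator
#'
#' The adjusted analysis compares arm means of cluster means of residuals
#' from a first-stage regression of Y on X (slope \eqn{\lambda}, fitted on
#' complete records pooled over arms, ignoring arm and clustering). For a
#' fixed first-stage slope,
#' \deqn{E(\hat\theta_{adj}^{obs}) = \mu_2-\mu_1 + \beta_2\mu_{x21} -
#'   \beta_1\mu_{x11} + \lambda(\mu_{x11}-\mu_{x21})}
#' on the arm2-minus-arm1 scale. Unbiased if both arms share covariate effect
#' and missingness mechanism, or if \eqn{\lambda = \beta_1 = \beta_2}.
#'
#' @inheritParams expected_bias_unadjusted
#' @param lambda First-stage slope (a fixed value or a probability limit from
#'   [plim_lambda_cra()]).
#' @return One-row tibble: `expected_estimate`, `bias`, `true_effect`.
#' @export
expected_bias_adjusted <- function(outcome, moments, lambda) {
  base <- expected_bias_unadjusted(outcome, moments)
  adj <- lambda * (moments$mu_x_obs[1] - moments$mu_x_obs[2])
  tibble::tibble(expected_estimate = base$expected_estimate + adj,
                 bias = base$bias + adj, true_effect = base$true_effect)
}

#' Variance of the adjusted cluster-level estimator under missingness
#'
#' \deqn{Var(\hat\theta_{adj}^{obs}) = \sum_i \frac{1}{k_i}\left(
#'   (\beta_i-\lambda)^2\sigma^2_{\bar x i1} + \sigma_b^2 +
#'   \sigma_{w,i}^2/\eta_i\right)}
#' At \eqn{\lambda = 0} this equals [var_unadjusted()]; over \eqn{\lambda} it
#' is a parabola minimised at the \eqn{\sigma^2_{\bar x}}-weighted mean of the
#' per-arm covariate effects, hence at \eqn{\beta} when the arms share it.
#'
#' @inheritParams var_unadjusted
#' @param lambda First-stage slope.
#' @return Scalar variance.
#' @export
var_adjusted <- function(outcome, design, moments, lambda) {
  stopifnot(inherits(design, "crt_design"), nrow(moments) == 2)
  per_arm <- (outcome$beta - lambda)^2 * moments$sigma2_xbar_obs +
    outcome$sigma_b2 + outcome$sigma_w2 / moments$eta
  sum(per_arm / design$k)
}

#' Probability limit of the first-stage pooled OLS slope on complete records
#'
#' The first-stage model regresses Y on X over complete records pooled across
#' arms, with no arm indicator. Its slope converges to
#' \eqn{Cov(X, Y | R=1) / Var(X | R=1)} under the pooled observed-data
#' distribution, an equal mixture over arms weighted by each arm's share of
#' observed records. Within arm i, \eqn{Cov(X,Y|R=1) = \beta_i Var(X|R=1)}
#' and \eqn{E(Y|R=1) = \alpha_i + \beta_i \mu_{xi1}}; the arm-mean outcome
#' difference feeds the pooled covariance through the between-arm covariate
#' shift whenever the two arms select differently on X, which is what biases
#' the pooled slope in those conditions.
#'
#' @param outcome An [outcome_params()].
#' @param miss A [missingness_params()].
#' @param design A [trial_design()] giving the arm sizes used for the mixing
#'   weights (equal total individuals per arm gives weights proportional to
#'   each arm's observation probability).
#' @return Scalar probability limit of the slope.
#' @export
plim_lambda_cra <- function(outcome, miss, design = trial_design()) {
  m <- design$m[[1]][1]
  mom <- arm_moments(miss, m)
  n_arm <- vapply(design$m, sum, numeric(1))
  w <- n_arm * mom$p_obs
  w <- w / sum(w)
  ex  <- sum(w * mom$mu_x_obs)
  ex2 <- sum(w * (mom$var_x_obs + mom$mu_x_obs^2))
  ey  <- sum(w * (outcome$alpha + outcome$beta * mom$mu_x_obs))
  exy <- sum(w * (outcome$beta * (mom$var_x_obs + mom$mu_x_obs^2) +
                    outcome$alpha * mom$mu_x_obs))
  (exy - ex * ey) / (ex2 - ex^2)
}

#' Analytic summary of the cluster-level estimators for a scenario
#'
#' Evaluates, per arm, the selection moments, and the expected bias and
#' variance of the unadjusted and adjusted cluster-level complete-records
#' estimators (the adjusted one at the probability limit of the first-stage
#' slope).
#'
#' @param scenario A [make_scenario()] object.
#' @return A one-row tibble with columns `scenario`, `k`, `rho`,
#'   `p_obs_1`, `p_obs_2`, `mu_x_obs_1`, `mu_x_obs_2`, `lambda_plim`,
#'   `bias_unadj`, `bias_adj`, `var_unadj`, `var_adj`.
#' @examples
#' theory_summary(make_scenario(4))
#' @export
theory_summary <- function(scenario) {
  stopifnot(inherits(scenario, "crt_scenario"))
  m <- scenario$design$m[[1]][1]
  mom <- arm_moments(scenario$missingness, m)
  lam <- plim_lambda_cra(scenario$outcome, scenario$missingness, scenario$design)
  bias_u <- expected_bias_unadjusted(scenario$outcome, mom)$bias
  bias_a <- expected_bias_adjusted(scenario$outcome, mom, lam)$bias
  v_u <- var_unadjusted(scenario$outcome, scenario$design, mom)
  v_a <- var_adjusted(scenario$outcome, scenario$design, mom, lam)
  sc_id <- scenario$id
  sc_k <- scenario$design$k[1]
  sc_rho <- scenario$outcome$rho
  tibble::tibble(
    scenario = sc_id,
    k = sc_k,
    rho = sc_rho,
    p_obs_1 = mom$p_obs[1], p_obs_2 = mom$p_obs[2],
    mu_x_obs_1 = mom$mu_x_obs[1], mu_x_obs_2 = mom$mu_x_obs[2],
    lambda_plim = lam,
    bias_unadj = bias_u,
    bias_adj = bias_a,
    var_unadj = v_u,
    var_adj = v_a
  )
}
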