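#' Per-cluster summaries of observed outcomes or residuals
#'
#' First stage of a cluster-level analysis: for every cluster, the mean of
#' the observed (`r == 1`) values and the observed count. Clusters with no
#' observed outcomes are excluded (their mean is undefined) and flagged.
#'
#' @param data A CRT dataset tibble.
#' @param values `"outcome"` (cluster means of y) or `"residual"` (cluster
#'   means of first-stage residuals; see [fit_stage_one()]).
#' @param stage_one Optional [fit_stage_one()] result to reuse when
#'   `values = "residual"`; fitted on the fly if omitted.
#' @return A tibble with columns `arm`, `cluster`, `n_observed`,
#'   `mean_observed`, carrying attribute `dropped` (tibble of excluded
#'   clusters, if any).
#' @examples
#' d <- generate_complete(trial_design(5, 10), outcome_params(), seed = 1)
#' cluster_means(d)
#' @export
cluster_means <- function(data, values = c("outcome", "residual"),
                          stage_one = NULL) {
  data <- check_crt_data(data)
  values <- match.arg(values)
  if (values == "residual") {
    if (is.null(stage_one)) stage_one <- fit_stage_one(data)
    data$value <- data$y - (stage_one$gamma + stage_one$lambda * data$x)
  } else {
    data$value <- data$y
  }
  # flat cluster key (rowsum is much faster than a grouped summarise here,
  # and this sits on the innermost loop of the simulation harness)
  span <- max(data$cluster) + 1L
  id <- (data$arm - 1L) * span + data$cluster
  all_ids <- sort(unique(id))
  obs <- data$r == 1
  sums <- rowsum(data$value[obs], id[obs])
  ids_obs <- as.integer(rownames(sums))
  counts <- rowsum(rep(1L, sum(obs)), id[obs])[, 1]
  out <- tibble::tibble(
    arm = ids_obs %/% span + 1L,
    cluster = ids_obs %% span,
    n_observed = as.integer(counts),
    mean_observed = unname(sums[, 1] / counts)
  )
  dropped_ids <- setdiff(all_ids, ids_obs)
  dropped <- tibble::tibble(arm = dropped_ids %/% span + 1L,
                            cluster = dropped_ids %% span)
  if (nrow(dropped)) {
    warning(nrow(dropped), " cluster(s) with no observed outcomes dropped",
            call. = FALSE)
  }
  k_arm <- tabulate(out$arm, 2)
  if (any(k_arm < 2)) {
    stop("fewer than 2 usable clusters in an arm: cluster-level inference impossible",
         call. = FALSE)
  }
  attr(out, "dropped") <- dropped
  out
}

# Pooled-variance two-sample t-test of arm-2 vs arm-1 cluster summaries,
# reported on the arm2-minus-arm1 scale.
cluster_ttest <- function(summaries, method_id, ci_level, df_drop = 0,
                          warnings = character()) {
  s1 <- summaries$mean_observed[summaries$arm == 1]
  s2 <- summaries$mean_observed[summaries$arm == 2]
  k1 <- length(s1); k2 <- length(s2)
  est <- mean(s2) - mean(s1)
  sp2 <- ((k1 - 1) * stats::var(s1) + (k2 - 1) * stats::var(s2)) / (k1 + k2 - 2)
  se <- sqrt(sp2 * (1 / k1 + 1 / k2))
  df <- k1 + k2 - 2 - df_drop
  new_method_result(method_id, est, se, df, ci_level, warnings)
}

# Common constructor for one-row method-result tibbles.
new_method_result <- function(method_id, estimate, se, df, ci_level,
                              warnings = character()) {
  tcrit <- stats::qt(1 - (1 - ci_level) / 2, df)
  tval <- estimate / se
  out <- tibble::tibble(
    method_id = method_id,
    estimate = estimate,
    se = se,
    df = df,
    ci_low = estimate - tcrit * se,
    ci_high = estimate + tcrit * se,
    p_value = 2 * stats::pt(-abs(tval), df),
    warnings = list(warnings)
  )
  class(out) <- c("crt_result", class(out))
  out
}

#' Unadjusted cluster-level analysis on complete records
#'
#' Two-stage analysis: cluster means of observed outcomes, compared across
#' arms by the pooled-variance (Student) two-sample t-test with
#' `k1 + k2 - 2` degrees of freedom. The intervention effect is reported as
#' arm 2 minus arm 1.
#'
#' @param data A CRT dataset tibble.
#' @param ci_level Confidence level (default 0.95).
#' @return A one-row `crt_result` tibble: `method_id`, `estimate`, `se`,
#'   `df`, `ci_low`, `ci_high`, `p_value`, `warnings` (list column).
#' @examples
#' d <- generate_complete(trial_design(10, 30), outcome_params(), seed = 1)
#' cl_unadjusted(d)
#' @export
cl_unadjusted <- function(data, ci_level = 0.95) {
  warns <- character()
  cs <- withCallingHandlers(
    cluster_means(data, "outcome"),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  cluster_ttest(cs, "cl-unadj", ci_level, warnings = warns)
}

#' First-stage individual-level regression for the adjusted analysis
#'
#' Ordinary least squares of y on x over complete records pooled across both
#' arms, deliberately omitting the intervention indicator and ignoring
#' clustering, exactly as the two-stage adjusted cluster-level analysis
#' prescribes. Under differential selection between arms this pooled slope is
#' inconsistent for the covariate effect, which is the source of the adjusted
#' analysis's residual bias (see [plim_lambda_cra()]).
#'
#' @param data A CRT dataset tibble.
#' @return A list of class `crt_stage_one`: `gamma` (intercept), `lambda`
#'   (slope), `n_used`.
#' @export
fit_stage_one <- function(data) {
  data <- check_crt_data(data)
  keep <- data$r == 1
  x <- data$x[keep]; y <- data$y[keep]
  if (length(x) < 2 || stats::var(x) == 0) {
    stop("first-stage regression needs >= 2 observed records with distinct x",
         call. = FALSE)
  }
  # simple-regression OLS in closed form (equals lm(y ~ x))
  lambda <- stats::cov(x, y) / stats::var(x)
  gamma <- mean(y) - lambda * mean(x)
  structure(list(gamma = gamma, lambda = lambda, n_used = length(x)),
            class = "crt_stage_one")
}

#' Covariate-adjusted cluster-level analysis on complete records
#'
#' Two-stage analysis: residuals from the pooled first-stage regression of y
#' on x ([fit_stage_one()]), averaged per cluster over observed records, then
#' compared across arms by the pooled-variance t-test. Degrees of freedom are
#' `k1 + k2 - 2 - p` where `p` counts cluster-level covariates in the first
#' stage (0 here: the single baseline covariate is individual-level).
#'
#' @inheritParams cl_unadjusted
#' @param p_cluster_covariates Number of cluster-level covariate parameters
#'   in the first-stage model (degrees-of-freedom reduction).
#' @return A one-row `crt_result` tibble.
#' @export
cl_adjusted <- function(data, ci_level = 0.95, p_cluster_covariates = 0) {
  data <- check_crt_data(data)
  s1 <- fit_stage_one(data)
  warns <- character()
  cs <- withCallingHandlers(
    cluster_means(data, "residual", stage_one = s1),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
    })
  res <- cluster_ttest(cs, "cl-adj", ci_level, df_drop = p_cluster_covariates,
                       warnings = warns)
  attr(res, "stage_one") <- s1
  res
}

#' Adjusted (design-effect) t-test on individual outcomes
#'
#' Compares the two arms' means of individual outcomes with a standard error
#' inflated for intracluster correlation: the variance of each arm mean is
#' \eqn{\hat\sigma^2 C_i / N_i} with design effect
#' \eqn{C_i = 1 + (\bar m_{Ai} - 1)\hat\rho}, where \eqn{\bar m_{Ai}} is the
#' cluster-size-weighted mean cluster size and \eqn{\hat\rho} the pooled
#' one-way-ANOVA intraclass correlation estimate computed after centring each
#' arm at its own mean. Degrees of freedom `k1 + k2 - 2`. On balanced
#' complete data this test is identical to the cluster-level t-test.
#'
#' A negative ANOVA estimate of the between-cluster variance is truncated to
#' zero (design effect 1) and flagged in `warnings`.
#'
#' @inheritParams cl_unadjusted
#' @return A one-row `crt_result` tibble.
#' @export
adjusted_ttest <- function(data, ci_level = 0.95) {
  data <- check_crt_data(data)
  keep <- data$r == 1
  y <- data$y[keep]; arm <- data$arm[keep]
  span <- max(data$cluster) + 1L
  id <- (arm - 1L) * span + data$cluster[keep]
  sums <- rowsum(y, id)
  ids <- as.integer(rownames(sums))
  n_cl <- rowsum(rep(1L, length(y)), id)[, 1]
  ybar_cl <- sums[, 1] / n_cl
  arm_cl <- ids %/% span + 1L
  k <- tabulate(arm_cl, 2)
  if (any(k < 2)) stop("fewer than 2 usable clusters in an arm", call. = FALSE)
  N <- tabulate(arm, 2)
  ybar_arm <- unname(rowsum(y, arm)[, 1]) / N
  J <- sum(k); Ntot <- sum(N)
  ssc <- sum(n_cl * (ybar_cl - ybar_arm[arm_cl])^2)
  ssw <- sum((y - ybar_cl[match(id, ids)])^2)
  msc <- ssc / (J - 2)
  msw <- ssw / (Ntot - J)
  # ANOVA cluster-size coefficient (equals m for balanced designs)
  sum_m2 <- unname(rowsum(as.numeric(n_cl)^2, arm_cl)[, 1])
  m_tilde <- (Ntot - sum(sum_m2 / N)) / (J - 2)
  sigma_b2 <- (msc - msw) / m_tilde
  warns <- character()
  if (sigma_b2 < 0) {
    warns <- "negative ANOVA between-cluster variance truncated to 0"
    sigma_b2 <- 0
  }
  sigma2 <- sigma_b2 + msw
  rho_hat <- sigma_b2 / sigma2
  m_bar <- sum_m2 / N                 # size-weighted mean cluster size per arm
  C <- 1 + (m_bar - 1) * rho_hat
  est <- ybar_arm[2] - ybar_arm[1]
  se <- sqrt(sum(sigma2 * C / N))
  res <- new_method_result("adj-t", est, se, J - 2, ci_level, warns)
  attr(res, "icc") <- rho_hat
  res
}
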