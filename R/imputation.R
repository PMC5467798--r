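#' Single imputation by cluster means or group means
#'
#' `impute_cluster_mean()` replaces each missing outcome by the mean of the
#' observed outcomes in its own cluster, which leaves every cluster mean
#' unchanged and (on balanced designs) makes the adjusted t-test after
#' imputation identical to the cluster-level t-test on the pre-imputation
#' observed records. `impute_group_mean()` replaces each missing outcome by
#' the mean of observed outcomes pooled over its arm, which shrinks the
#' between-cluster variability of cluster means. Both are single-imputation
#' methods: they understate uncertainty and are provided for studying their
#' behaviour, not as recommended practice.
#'
#' @param data A CRT dataset tibble.
#' @return The completed dataset (all `r == 1`).
#' @examples
#' d <- generate_scenario(make_scenario(1, k = 5), seed = 1)
#' dc <- impute_cluster_mean(d)
#' all(dc$r == 1)
#' @export
impute_cluster_mean <- function(data) {
  data <- check_crt_data(data)
  span <- max(data$cluster) + 1L
  id <- (data$arm - 1L) * span + data$cluster
  obs <- data$r == 1
  sums <- rowsum(data$y[obs], id[obs])
  ids <- as.integer(rownames(sums))
  empty <- setdiff(unique(id), ids)
  if (length(empty)) {
    lab <- paste0("arm ", empty %/% span + 1L, " cluster ", empty %% span)
    stop("cannot impute: no observed outcomes in ",
         paste(lab, collapse = "; "), call. = FALSE)
  }
  n_obs <- rowsum(rep(1L, sum(obs)), id[obs])[, 1]
  fill <- (sums[, 1] / n_obs)[match(id, ids)]
  data$y <- ifelse(obs, data$y, fill)
  data$r <- 1L
  data
}

#' @rdname impute_cluster_mean
#' @export
impute_group_mean <- function(data) {
  data <- check_crt_data(data)
  filled <- data |>
    dplyr::group_by(.data$arm) |>
    dplyr::mutate(.n_obs = sum(.data$r),
                  .fill = ifelse(.data$.n_obs > 0,
                                 sum(.data$y * .data$r) / pmax(.data$.n_obs, 1),
                                 NA_real_)) |>
    dplyr::ungroup()
  if (any(filled$.n_obs == 0)) {
    stop("cannot impute: an arm has no observed outcomes", call. = FALSE)
  }
  filled |>
    dplyr::mutate(y = ifelse(.data$r == 1, .data$y, .data$.fill), r = 1L) |>
    dplyr::select(-".n_obs", -".fill")
}

#' Random-effects multiple imputation of missing outcomes
#'
#' Imputes missing outcomes from a Bayesian random-intercept linear mixed
#' model fitted by a Gibbs sampler. The imputation model has fixed effects
#' for the baseline covariate and the intervention indicator (plus their
#' interaction on the empirically centred covariate when
#' `interaction = TRUE`, matching the analysis model), a normal random
#' intercept per cluster, and normal individual errors. Priors: improper
#' flat on the fixed effects, inverse-gamma(0.001, 0.001) on both the
#' between-cluster and within-cluster variances.
#'
#' The sampler cycles through the full conditionals of the fixed effects,
#' the cluster intercepts and the two variances given the observed outcomes;
#' after `burn_in` iterations, every `thin`-th state yields one completed
#' dataset by drawing each missing outcome from its normal predictive
#' distribution given the current parameters. Initial values come from OLS
#' on the observed records, with the between-cluster variance started at the
#' ANOVA moment estimate floored at 1% of the residual variance.
#'
#' @param data A CRT dataset with some `r == 0` records (a dataset with no
#'   missing values returns `Q` identical copies).
#' @param Q Number of imputations (at least 2; default 20).
#' @param burn_in Burn-in iterations (default 200).
#' @param thin Iterations between successive retained draws (default 10).
#' @param interaction Include intervention-by-centred-covariate interaction
#'   in the imputation model?
#' @param seed Optional integer seed.
#' @return A list of class `crt_mi_stack`: `datasets` (list of Q completed
#'   tibbles), `Q`, `interaction`, and `trace` (tibble of retained parameter
#'   draws: fixed effects, `sigma_b2`, `sigma_w2`) for mixing diagnostics.
#' @examples
#' d <- generate_scenario(make_scenario(1, k = 5), seed = 1)
#' st <- mi_impute(d, Q = 2, burn_in = 20, thin = 2, seed = 2)
#' length(st$datasets)
#' @export
mi_impute <- function(data, Q = 20, burn_in = 200, thin = 10,
                      interaction = FALSE, seed = NULL) {
  if (Q < 2) stop("Q must be at least 2", call. = FALSE)
  df <- lmm_frame(data)
  if (!is.null(seed)) set.seed(seed)
  if (all(df$r == 1)) {
    datasets <- replicate(Q, dplyr::select(df, "arm", "cluster", "individual",
                                           "x", "y", "r"), simplify = FALSE)
    return(structure(list(datasets = datasets, Q = Q, interaction = interaction,
                          trace = NULL), class = "crt_mi_stack"))
  }
  X <- if (interaction) cbind(1, df$xc, df$z, df$xc * df$z) else cbind(1, df$x, df$z)
  colnames(X) <- if (interaction) c("(Intercept)", "xc", "z", "xc:z") else
    c("(Intercept)", "x", "z")
  cl <- as.integer(factor(df$cl_id, levels = unique(df$cl_id)))
  J <- max(cl)
  obs <- df$r == 1
  Xo <- X[obs, , drop = FALSE]; yo <- df$y[obs]; clo <- cl[obs]
  Xm <- X[!obs, , drop = FALSE]; clm <- cl[!obs]
  n_obs <- length(yo); p <- ncol(X)
  nj <- tabulate(clo, J)

  # per-cluster sums robust to clusters with no observed records
  cluster_sums <- function(v) {
    out <- numeric(J)
    s <- rowsum(v, clo)
    out[as.integer(rownames(s))] <- s[, 1]
    out
  }

  XtXi <- chol2inv(chol(crossprod(Xo)))
  R_XtXi <- chol(XtXi)           # for correlated normal draws of beta
  a0 <- b0 <- 0.001

  # init from OLS + ANOVA moments
  beta <- drop(XtXi %*% crossprod(Xo, yo))
  resid <- yo - drop(Xo %*% beta)
  sw2 <- stats::var(resid)
  cl_means <- cluster_sums(resid) / pmax(nj, 1)
  sb2 <- max(stats::var(cl_means[nj > 0]) - sw2 * mean(1 / nj[nj > 0]),
             0.01 * sw2)
  u <- rep(0, J)

  n_iter <- burn_in + thin * Q
  keep_at <- burn_in + thin * seq_len(Q)
  datasets <- vector("list", Q)
  trace <- matrix(NA_real_, Q, p + 2,
                  dimnames = list(NULL, c(colnames(X), "sigma_b2", "sigma_w2")))
  qi <- 1L
  for (it in seq_len(n_iter)) {
    # beta | u, sw2: N(XtXi X'(y-u), sw2 XtXi)
    bhat <- drop(XtXi %*% crossprod(Xo, yo - u[clo]))
    beta <- bhat + sqrt(sw2) * drop(crossprod(R_XtXi, stats::rnorm(p)))
    # u_j | beta, sw2, sb2
    rj <- cluster_sums(yo - drop(Xo %*% beta))
    prec <- nj / sw2 + 1 / sb2
    u <- stats::rnorm(J, (rj / sw2) / prec, sqrt(1 / prec))
    # variances | rest
    ss_w <- sum((yo - drop(Xo %*% beta) - u[clo])^2)
    sw2 <- 1 / stats::rgamma(1, a0 + n_obs / 2, b0 + ss_w / 2)
    sb2 <- 1 / stats::rgamma(1, a0 + J / 2, b0 + sum(u^2) / 2)
    if (!is.finite(sw2) || !is.finite(sb2)) {
      stop("Gibbs sampler divergence: non-finite variance draw at iteration ", it,
           call. = FALSE)
    }
    if (it == keep_at[qi]) {
      y_mis <- drop(Xm %*% beta) + u[clm] + stats::rnorm(nrow(Xm), 0, sqrt(sw2))
      comp <- df
      comp$y[!obs] <- y_mis
      comp$r <- 1L
      datasets[[qi]] <- dplyr::select(comp, "arm", "cluster", "individual",
                                      "x", "y", "r")
      trace[qi, ] <- c(beta, sb2, sw2)
      if (qi == Q) break
      qi <- qi + 1L
    }
  }
  structure(list(datasets = datasets, Q = Q, interaction = interaction,
                 trace = tibble::as_tibble(trace)),
            class = "crt_mi_stack")
}

#' Combine per-imputation estimates by Rubin's rules
#'
#' Pools Q point estimates and variances: pooled estimate `qbar` (mean),
#' within-imputation variance `W` (mean of variances), between-imputation
#' variance `B` (sample variance of estimates), total variance
#' `W + (1 + 1/Q) B`. The reference t distribution uses the Barnard-Rubin
#' small-sample adjusted degrees of freedom
#' \deqn{\nu_{adj} = (1/\nu + 1/\hat\nu_{obs})^{-1} \le \nu_{com}}
#' where \eqn{\nu = (Q-1)\{1 + Q W / ((Q+1) B)\}^2} is the classical
#' repeated-imputation df (derived assuming infinite complete-data df) and
#' \deqn{\hat\nu_{obs} = \Big(1 + \frac{(Q+1)B}{Q W}\Big)^{-1}
#'   \frac{\nu_{com}+1}{\nu_{com}+3}\,\nu_{com}.}
#' With no between-imputation variance (`B = 0`) the limit
#' \eqn{\nu \to \infty}, \eqn{\nu_{adj} = \hat\nu_{obs}} is used.
#'
#' @param estimates Numeric vector of per-imputation point estimates.
#' @param variances Numeric vector of per-imputation squared standard errors.
#' @param nu_com Complete-data degrees of freedom (for cluster randomised
#'   trials, based on the number of clusters: `2(k - 1)` per the balanced
#'   convention).
#' @param ci_level Confidence level.
#' @return A one-row tibble of class `crt_mi_pooled`: `qbar`, `W`, `B`,
#'   `total_var`, `nu`, `nu_com`, `nu_obs`, `nu_adj`, `ci_low`, `ci_high`,
#'   `p_value`, `Q`.
#' @examples
#' pool_rubin(c(4.8, 5.1, 5.3), c(1, 1, 1), nu_com = 18)
#' @export
pool_rubin <- function(estimates, variances, nu_com, ci_level = 0.95) {
  Q <- length(estimates)
  stopifnot(Q >= 2, length(variances) == Q, all(variances > 0), nu_com > 0)
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- stats::var(estimates)
  total_var <- W + (1 + 1 / Q) * B
  if (B > 0) {
    nu <- (Q - 1) * (1 + Q * W / ((Q + 1) * B))^2
    nu_obs <- (1 / (1 + (Q + 1) * B / (Q * W))) *
      ((nu_com + 1) / (nu_com + 3)) * nu_com
    nu_adj <- 1 / (1 / nu + 1 / nu_obs)
  } else {
    nu <- Inf
    nu_obs <- ((nu_com + 1) / (nu_com + 3)) * nu_com
    nu_adj <- nu_obs
  }
  se <- sqrt(total_var)
  tcrit <- stats::qt(1 - (1 - ci_level) / 2, nu_adj)
  out <- tibble::tibble(
    qbar = qbar, W = W, B = B, total_var = total_var,
    nu = nu, nu_com = nu_com, nu_obs = nu_obs, nu_adj = nu_adj,
    ci_low = qbar - tcrit * se, ci_high = qbar + tcrit * se,
    p_value = 2 * stats::pt(-abs(qbar / se), nu_adj), Q = Q
  )
  class(out) <- c("crt_mi_pooled", class(out))
  out
}

#' Analyse a multiply imputed stack by LMM and pool
#'
#' Fits the random-intercept LMM (REML, [fit_lmm_cra()] model) to each
#' completed dataset — the interaction flag follows the stack's imputation
#' model — and pools the intervention-effect estimates by Rubin's rules with
#' complete-data degrees of freedom `nu_com = 2(k - 1)`. The reported `df`
#' is the Barnard-Rubin `nu_adj`. Per-dataset convergence failures are
#' dropped and flagged when below 10% of the stack; more than that is an
#' error.
#'
#' @param stack A [mi_impute()] result.
#' @param ci_level Confidence level.
#' @return A one-row `crt_result` tibble (method `"mi"`); the full pooling
#'   record is attached as attribute `pooled`.
#' @export
mi_analyze <- function(stack, ci_level = 0.95) {
  stopifnot(inherits(stack, "crt_mi_stack"))
  spec <- lmm_spec(interaction = stack$interaction)
  first <- lmm_frame(stack$datasets[[1]])
  k_used <- dplyr::n_distinct(first$cl_id[first$arm == 1])
  nu_com <- 2 * (k_used - 1)
  form <- if (spec$interaction) y ~ xc * z + (1 | cl_id) else y ~ x + z + (1 | cl_id)
  base <- fit_lmer_robust(form, first)
  ests <- vars <- rep(NA_real_, stack$Q)
  warns <- character()
  extract <- function(f) c(unname(lme4::fixef(f)[["z"]]),
                           as.matrix(stats::vcov(f))["z", "z"])
  if (!is.null(base$fit) && !"nonconvergence" %in% base$warnings) {
    ev <- extract(base$fit)
    ests[1] <- ev[1]; vars[1] <- ev[2]
  }
  for (q in seq_len(stack$Q)[-1]) {
    newy <- lmm_frame(stack$datasets[[q]])$y
    fq <- tryCatch(
      suppressMessages(suppressWarnings(
        if (!is.null(base$fit)) lme4::refit(base$fit, newresp = newy) else NULL)),
      error = function(e) NULL)
    if (is.null(fq)) {
      fq <- fit_lmer_robust(form, lmm_frame(stack$datasets[[q]]))$fit
    }
    if (!is.null(fq)) {
      ev <- extract(fq)
      ests[q] <- ev[1]; vars[q] <- ev[2]
    }
  }
  ok <- is.finite(ests) & is.finite(vars) & vars > 0
  n_fail <- sum(!ok)
  if (n_fail > 0) {
    if (n_fail > 0.1 * stack$Q) {
      stop("LMM failed on ", n_fail, " of ", stack$Q, " completed datasets",
           call. = FALSE)
    }
    warns <- paste0(n_fail, " completed dataset(s) dropped for non-convergence")
  }
  pooled <- pool_rubin(ests[ok], vars[ok], nu_com, ci_level)
  res <- tibble::tibble(
    method_id = "mi", estimate = pooled$qbar, se = sqrt(pooled$total_var),
    df = pooled$nu_adj, ci_low = pooled$ci_low, ci_high = pooled$ci_high,
    p_value = pooled$p_value, warnings = list(warns)
  )
  class(res) <- c("crt_result", class(res))
  attr(res, "pooled") <- pooled
  res
}
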