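test_that("selection moments match an independent Monte Carlo oracle", {
  set.seed(71)
  n <- 2e6
  x <- rnorm(n)
  for (phi0 in c(-1, 0.5)) {
    keep <- runif(n) < plogis(-phi0 - x)
    mom <- selection_moments(phi0, 1, m = 30)
    expect_lt(abs(mom$p_obs - mean(keep)), 3 * sd(keep) / sqrt(n))
    xk <- x[keep]
    expect_lt(abs(mom$mu_x_obs - mean(xk)), 3 * sd(xk) / sqrt(length(xk)))
    expect_equal(mom$var_x_obs, var(xk), tolerance = 0.01)
  }
  # frozen oracle values for the two study mechanisms
  m1 <- selection_moments(-1, 1)
  expect_equal(m1$p_obs, 0.69673, tolerance = 1e-4)
  expect_equal(m1$mu_x_obs, -0.25540, tolerance = 1e-4)
  m2 <- selection_moments(0.5, 1)
  expect_equal(m2$p_obs, 0.39797, tolerance = 1e-4)
  expect_equal(m2$mu_x_obs, -0.5, tolerance = 1e-3)
})

test_that("selection independent of x leaves the covariate law untouched", {
  mom <- selection_moments(0.3, 0, m = 30)
  expect_equal(mom$mu_x_obs, 0, tolerance = 1e-8)
  expect_equal(mom$var_x_obs, 1, tolerance = 1e-8)
  expect_equal(mom$p_obs, plogis(-0.3), tolerance = 1e-10)
  expect_lte(mom$eta, 30 * mom$p_obs + 1e-9)
})

test_that("the effective observed cluster size matches simulated E(1/n)", {
  mom <- selection_moments(0.5, 1, m = 30)
  set.seed(73)
  n_obs <- rbinom(2e5, 30, mom$p_obs)
  n_obs <- n_obs[n_obs >= 1]
  sim <- mean(1 / n_obs)
  expect_lt(abs(1 / mom$eta - sim), 3 * sd(1 / n_obs) / sqrt(length(n_obs)))
})

test_that("expected bias of the unadjusted estimator follows the moment formula", {
  m30 <- 30
  mom_same <- dplyr::bind_rows(selection_moments(-1, 1, m30),
                               selection_moments(-1, 1, m30))
  mom_diff <- dplyr::bind_rows(selection_moments(-1, 1, m30),
                               selection_moments(0.5, 1, m30))
  # scenario 1: shared effect and mechanism, bias exactly 0
  b1 <- expected_bias_unadjusted(outcome_params(tau = 0.5), mom_same)
  expect_equal(b1$bias, 0, tolerance = 1e-12)
  expect_equal(b1$expected_estimate, 5)
  # scenario 3: beta (4,6), shared mechanism: bias = 2 * mu_x_obs
  b3 <- expected_bias_unadjusted(outcome_params(tau = c(0.4, 0.6)), mom_same)
  expect_equal(b3$bias, 2 * (-0.25540), tolerance = 1e-4)
  # scenario 4: 6 * (-0.5) - 4 * (-0.2554)
  b4 <- expected_bias_unadjusted(outcome_params(tau = c(0.4, 0.6)), mom_diff)
  expect_equal(b4$bias, -1.97842, tolerance = 1e-4)
})

test_that("adjusted-estimator bias adds the first-stage slope correction", {
  m30 <- 30
  mom_same <- dplyr::bind_rows(selection_moments(-1, 1, m30),
                               selection_moments(-1, 1, m30))
  mom_diff <- dplyr::bind_rows(selection_moments(-1, 1, m30),
                               selection_moments(0.5, 1, m30))
  # lambda = beta1 = beta2: unbiased regardless of differing mechanisms
  op_eq <- outcome_params(tau = 0.5)
  expect_equal(expected_bias_adjusted(op_eq, mom_diff, lambda = 5)$bias, 0,
               tolerance = 1e-10)
  # equal selection: the lambda term vanishes, bias as unadjusted
  op34 <- outcome_params(tau = c(0.4, 0.6))
  expect_equal(expected_bias_adjusted(op34, mom_same, lambda = 5)$bias,
               expected_bias_unadjusted(op34, mom_same)$bias, tolerance = 1e-10)
  # scenario 1 with any lambda: both correction terms vanish
  expect_equal(expected_bias_adjusted(op_eq, mom_same, lambda = 2.7)$bias, 0,
               tolerance = 1e-10)
})

test_that("unbiasedness holds exactly when beta1 mu11 equals beta2 mu21", {
  m30 <- 30
  grid <- tidyr::expand_grid(phi0_1 = c(-1, 0, 0.5), phi0_2 = c(-1, 0.5),
                             tau1 = c(0.3, 0.5))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    mom <- dplyr::bind_rows(selection_moments(g$phi0_1, 1, m30),
                            selection_moments(g$phi0_2, 1, m30))
    # choose tau2 to satisfy the balance condition, when feasible
    tau2 <- g$tau1 * mom$mu_x_obs[1] / mom$mu_x_obs[2]
    if (abs(tau2) < 0.9) {
      op <- outcome_params(tau = c(g$tau1, tau2))
      expect_equal(expected_bias_unadjusted(op, mom)$bias, 0, tolerance = 1e-10)
    }
    # and violate it: bias nonzero
    op_off <- outcome_params(tau = c(g$tau1, min(0.9, g$tau1 + 0.2)))
    bias <- expected_bias_unadjusted(op_off, mom)$bias
    cond <- op_off$beta[1] * mom$mu_x_obs[1] - op_off$beta[2] * mom$mu_x_obs[2]
    expect_equal(bias, -cond, tolerance = 1e-10)
  }
})

test_that("estimator variance formulas obey their structural limits", {
  des <- trial_design(k = 10, m = 30)
  op0 <- outcome_params(tau = 0, rho = 0.05)
  # no missingness, no covariate effect: sum of (sigma_b2 + sigma_w2 / m) / k
  mom_full <- tibble::tibble(p_obs = 1, mu_x_obs = 0, var_x_obs = 1,
                             eta = 30, sigma2_xbar_obs = 1 / 30)
  mom_full <- dplyr::bind_rows(mom_full, mom_full)
  expect_equal(var_unadjusted(op0, des, mom_full),
               2 * (5 + 95 / 30) / 10, tolerance = 1e-12)
  # doubling k halves the variance
  op <- outcome_params(tau = 0.5, rho = 0.05)
  mom <- dplyr::bind_rows(selection_moments(-1, 1, 30),
                          selection_moments(-1, 1, 30))
  expect_equal(var_unadjusted(op, trial_design(k = 20, m = 30), mom),
               var_unadjusted(op, des, mom) / 2, tolerance = 1e-12)
  # scenario 1 cell value, frozen from the plug-in evaluation
  expect_equal(var_unadjusted(op, des, mom), 1.8889, tolerance = 1e-3)
})

test_that("adjusted variance is a parabola in lambda minimised near beta", {
  des <- trial_design(k = 10, m = 30)
  op <- outcome_params(tau = 0.5, rho = 0.05)
  mom <- dplyr::bind_rows(selection_moments(-1, 1, 30),
                          selection_moments(0.5, 1, 30))
  # lambda = 0 reduces exactly to the unadjusted variance
  expect_equal(var_adjusted(op, des, mom, lambda = 0),
               var_unadjusted(op, des, mom), tolerance = 1e-14)
  # lambda = beta strictly below the unadjusted variance when beta != 0
  expect_lt(var_adjusted(op, des, mom, lambda = 5),
            var_unadjusted(op, des, mom))
  # vertex at the sigma2_xbar-weighted mean of the per-arm betas
  lams <- seq(-2, 12, by = 0.05)
  vals <- vapply(lams, function(l) var_adjusted(op, des, mom, l), numeric(1))
  vertex <- lams[which.min(vals)]
  w <- mom$sigma2_xbar_obs / des$k
  expect_equal(vertex, sum(w * op$beta) / sum(w), tolerance = 0.05)
})

test_that("the pooled first-stage slope limit matches a Monte Carlo OLS oracle", {
  # shared selection and effect: limit is exactly beta
  op1 <- outcome_params(tau = 0.5)
  expect_equal(plim_lambda_cra(op1, missingness_params(-1, 1)), 5,
               tolerance = 1e-6)
  # no selection on x: limit is beta even with differing intercepts
  expect_equal(plim_lambda_cra(op1, missingness_params(c(-1, 0.5), 0)), 5,
               tolerance = 1e-6)
  # scenario 2: biased limit, cross-checked by simulation
  miss2 <- missingness_params(c(-1, 0.5), 1)
  plim2 <- plim_lambda_cra(op1, miss2)
  expect_gt(abs(plim2 - 5), 0.1)
  set.seed(79)
  n <- 5e5
  sim <- purrr::map(1:2, function(i) {
    x <- rnorm(n)
    y <- op1$alpha[i] + op1$beta[i] * x +
      rnorm(n, 0, sqrt(op1$sigma_b2 + op1$sigma_w2[i]))
    keep <- runif(n) < plogis(-miss2$phi0[i] - x)
    list(x = x[keep], y = y[keep])
  })
  xs <- c(sim[[1]]$x, sim[[2]]$x); ys <- c(sim[[1]]$y, sim[[2]]$y)
  slope <- cov(xs, ys) / var(xs)
  se <- sqrt(var(ys - mean(ys) - slope * (xs - mean(xs))) /
               (length(xs) * var(xs)))
  expect_lt(abs(plim2 - slope), 4 * se)
})

test_that("theory summary reproduces the per-scenario headline quantities", {
  th <- purrr::map(1:4, function(id) theory_summary(make_scenario(id))) |>
    dplyr::bind_rows()
  expect_equal(th$bias_unadj, c(0, -1.2230, -0.5108, -1.9784), tolerance = 1e-3)
  expect_equal(th$p_obs_1, rep(0.69673, 4), tolerance = 1e-4)
  expect_equal(th$p_obs_2, c(0.69673, 0.39797, 0.69673, 0.39797),
               tolerance = 1e-4)
  # scenario 1 is the only unbiased cell for both cluster-level analyses
  expect_equal(th$bias_adj[1], 0, tolerance = 1e-8)
  expect_true(all(abs(th$bias_adj[2:4]) > 0.01))
  expect_true(all(th$bias_unadj <= 0))
})
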