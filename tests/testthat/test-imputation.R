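test_that("cluster mean imputation fills from the cluster's observed mean", {
  d <- make_crt(list(list(c(1, 2, NA, 3), c(4, 6)), list(c(5, 7), c(8, 10))))
  dc <- impute_cluster_mean(d)
  expect_equal(dc$y[d$arm == 1 & d$cluster == 1], c(1, 2, 2, 3))
  expect_true(all(dc$r == 1))
  # cluster means unchanged by imputation
  pre <- cluster_means(d)$mean_observed
  post <- cluster_means(dc)$mean_observed
  expect_equal(post, pre)
  # no missing values: identity
  d0 <- make_crt(list(list(c(1, 2), c(3, 4)), list(c(5, 6), c(7, 8))))
  expect_equal(impute_cluster_mean(d0)$y, d0$y)
  # unimputable cluster is an error naming it
  dbad <- make_crt(list(list(c(NA, NA), c(1, 2)), list(c(3, 4), c(5, 6))))
  expect_error(impute_cluster_mean(dbad), "arm 1 cluster 1")
})

test_that("group mean imputation fills from the arm mean and shrinks cluster spread", {
  d <- make_crt(list(list(c(1, NA), c(3, 3)), list(c(5, 5), c(7, 7))))
  dg <- impute_group_mean(d)
  # arm-1 observed values {1, 3, 3} -> mean 7/3
  expect_equal(dg$y[d$arm == 1 & d$cluster == 1], c(1, 7 / 3))
  d0 <- make_crt(list(list(c(1, 2), c(3, 4)), list(c(5, 6), c(7, 8))))
  expect_equal(impute_group_mean(d0)$y, d0$y)
  # between-cluster variance of cluster means strictly shrinks when a value
  # is imputed and the cluster means differ
  dm <- generate_scenario(make_scenario(1, k = 6), seed = 41)
  v_pre <- var(cluster_means(dm)$mean_observed)
  v_post <- var(cluster_means(impute_group_mean(dm))$mean_observed)
  expect_lt(v_post, v_pre)
})

test_that("adjusted t-test after cluster mean imputation equals the pre-imputation cluster-level t-test", {
  d <- generate_scenario(make_scenario(2, k = 8), seed = 43)
  a <- cl_unadjusted(d)                      # observed records
  b <- adjusted_ttest(impute_cluster_mean(d))
  expect_equal(b$estimate, a$estimate, tolerance = 1e-12)
  expect_equal(b$se, a$se, tolerance = 1e-12)
  expect_equal(b$df, a$df)
})

test_that("Rubin/Barnard-Rubin pooling reproduces independent arithmetic", {
  Q <- 3; W <- 1; B <- 0.5; nu_com <- 18
  # independent evaluation of the pooling formulas
  nu_o <- (Q - 1) * (1 + Q * W / ((Q + 1) * B))^2
  nuobs_o <- (1 / (1 + (Q + 1) * B / (Q * W))) * ((nu_com + 1) / (nu_com + 3)) * nu_com
  nuadj_o <- 1 / (1 / nu_o + 1 / nuobs_o)
  expect_equal(nu_o, 12.5)
  expect_equal(nuobs_o, 9.7714, tolerance = 1e-4)
  expect_equal(nuadj_o, 5.484, tolerance = 1e-3)
  # feed estimates/variances whose sample moments are exactly (W, B)
  ests <- c(5 - sqrt(B), 5, 5 + sqrt(B))     # mean 5, var B
  pooled <- pool_rubin(ests, rep(W, Q), nu_com)
  expect_equal(pooled$qbar, 5)
  expect_equal(pooled$W, W)
  expect_equal(pooled$B, B)
  expect_equal(pooled$total_var, W + (1 + 1 / Q) * B)
  expect_equal(pooled$nu, nu_o)
  expect_equal(pooled$nu_obs, nuobs_o)
  expect_equal(pooled$nu_adj, nuadj_o)
})

test_that("pooling handles vanishing between-imputation variance as a limit", {
  pooled <- pool_rubin(rep(2, 5), rep(1.5, 5), nu_com = 18)
  expect_equal(pooled$nu, Inf)
  expect_equal(pooled$nu_adj, (19 / 21) * 18)
  expect_equal(pooled$total_var, 1.5)
})

test_that("adjusted df never exceeds the complete-data df", {
  set.seed(47)
  for (i in 1:50) {
    Q <- sample(2:30, 1)
    W <- runif(1, 0.1, 5)
    B <- runif(1, 0, 5)
    nu_com <- sample(3:60, 1)
    ests <- rnorm(Q, 0, sqrt(max(B, 1e-6)))
    p <- pool_rubin(ests, rep(W, Q), nu_com)
    expect_lte(p$nu_adj, p$nu_com + 1e-10)
    expect_lte(p$nu_adj, p$nu + 1e-10)
    expect_gte(p$B, 0)
  }
})

test_that("mi_impute preserves observed values and is seed-reproducible", {
  d <- generate_scenario(make_scenario(1, k = 5), seed = 51)
  stk <- mi_impute(d, Q = 3, burn_in = 30, thin = 3, seed = 52)
  expect_length(stk$datasets, 3)
  obs <- d$r == 1
  for (dd in stk$datasets) {
    expect_equal(dd$y[obs], d$y[obs])
    expect_true(all(dd$r == 1))
  }
  # the imputed (originally missing) values differ across imputations
  expect_false(identical(stk$datasets[[1]]$y[!obs], stk$datasets[[2]]$y[!obs]))
  stk2 <- mi_impute(d, Q = 3, burn_in = 30, thin = 3, seed = 52)
  expect_identical(stk$datasets, stk2$datasets)
  expect_error(mi_impute(d, Q = 1), "at least 2")
})

test_that("mi_impute with no missing data returns identical copies", {
  d <- generate_complete(trial_design(k = 4, m = 8), outcome_params(), seed = 53)
  stk <- mi_impute(d, Q = 4, seed = 54)
  expect_length(stk$datasets, 4)
  expect_identical(stk$datasets[[1]]$y, d$y)
  expect_identical(stk$datasets[[1]]$y, stk$datasets[[4]]$y)
})

test_that("Gibbs posterior tracks REML on the observed data", {
  d <- generate_scenario(make_scenario(1, k = 30, rho = 0.05), seed = 55)
  stk <- mi_impute(d, Q = 40, burn_in = 100, thin = 5, seed = 56)
  reml <- attr(fit_lmm_cra(d), "varcomp")
  # posterior means within a loose band of the REML point estimates
  expect_equal(mean(stk$trace$sigma_w2), unname(reml["sigma_w2"]),
               tolerance = 0.1)
  expect_lt(abs(mean(stk$trace$sigma_b2) - reml["sigma_b2"]), 4)
  # with no true clustering the between-cluster draws concentrate near zero
  d0 <- generate_complete(trial_design(k = 10, m = 60),
                          outcome_params(tau = 0.5, rho = 0), seed = 57)
  d0 <- impose_missingness(d0, missingness_params(-1, 1), seed = 58)
  stk0 <- mi_impute(d0, Q = 40, burn_in = 100, thin = 5, seed = 59)
  expect_lt(median(stk0$trace$sigma_b2), 3)  # 3% of the total variance 100
})

test_that("mi_analyze pools per-imputation LMM fits with nu_com = 2(k-1)", {
  d <- generate_scenario(make_scenario(1, k = 5), seed = 61)
  stk <- mi_impute(d, Q = 5, burn_in = 50, thin = 5, seed = 62)
  res <- mi_analyze(stk)
  pooled <- attr(res, "pooled")
  expect_equal(pooled$nu_com, 8)
  expect_equal(res$df, pooled$nu_adj)
  expect_lt(pooled$nu_adj, 8)
  # per-imputation fits pooled by Rubin's rules: recompute independently
  ests <- purrr::map_dbl(stk$datasets, function(dd) fit_lmm_cra(dd)$estimate)
  expect_equal(res$estimate, mean(ests), tolerance = 1e-4)
  # a stack of identical completed datasets degenerates to B = 0
  dcomp <- generate_complete(trial_design(k = 5, m = 10), outcome_params(),
                             seed = 63)
  stk0 <- mi_impute(dcomp, Q = 3, seed = 64)
  res0 <- mi_analyze(stk0)
  expect_equal(attr(res0, "pooled")$B, 0)
  expect_equal(res0$df, (9 / 11) * 8)
  expect_equal(res0$estimate, fit_lmm_cra(dcomp)$estimate, tolerance = 1e-6)
})
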