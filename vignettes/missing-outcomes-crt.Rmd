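---
title: "Covariate-dependent missing outcomes in cluster randomised trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariate-dependent missing outcomes in cluster randomised trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(crtmiss)
library(dplyr)
```

## The problem

In a cluster randomised trial (CRT), clusters — practices, schools, villages —
are randomised to control or intervention, and a continuous outcome is
measured on individuals within clusters. Outcomes within a cluster are
correlated; the intraclass correlation coefficient (ICC, $\rho$) is typically
between 0.001 and 0.1 for clinical outcomes. Attrition is common, and the
question this package studies is: when the probability that an outcome is
missing depends on a fully observed baseline covariate — *covariate dependent
missingness* (CDM), a special case of missing at random — which of the
standard CRT analyses still give unbiased, correctly-calibrated estimates of
the intervention effect, on complete records or after imputation?

## The data-generating model

For individual $l$ in cluster $j$ of arm $i$ ($i = 1$ control, $2$
intervention):

$$Y_{ijl} = \alpha_i + \beta_i X_{ijl} + \delta_{ij} + \epsilon_{ijl},$$

with $X_{ijl} \sim N(0,1)$ independently,
$\delta_{ij} \sim N(0, \sigma_b^2)$, and
$\epsilon_{ijl} \sim N(0, \sigma_{w,i}^2)$. Because $\mathrm{Var}(X) = 1$,
writing $\beta_i = \tau_i \sigma_y$ with $\tau_i$ the outcome–covariate
correlation and setting $\sigma_b^2 = \rho\sigma_y^2$,
$\sigma_{w,i}^2 = (1 - \tau_i^2 - \rho)\sigma_y^2$ keeps the total within-arm
variance at $\sigma_y^2$ and the unconditional ICC at $\rho$. The constructor
`outcome_params()` enforces $1 - \tau_i^2 - \rho > 0$.

Missingness is imposed per individual by a logistic selection model in the
baseline covariate only:

$$\mathrm{logit}\, P(R_{ijl} = 0 \mid X_{ijl}) = \varphi_{i0} + \varphi_{i1} X_{ijl},$$

where $R = 1$ marks an observed outcome. `impose_missingness()` masks by flag
(`r = 0`) and retains the true `y`, so bias diagnostics against the truth
never require regeneration; every analysis function uses `y` only where
`r == 1`.

## The four study scenarios

`make_scenario(id, k, rho)` fixes the shared constants
($\alpha = (20, 25)$ so the true effect is $5$; $\sigma_y^2 = 100$; cluster
size $m = 30$; $\varphi_{i1} = 1$, an odds ratio of $e \approx 2.72$ for
missingness per covariate unit) and crosses two factors:

| id | $\varphi_{10}, \varphi_{20}$ | $\tau_1, \tau_2$ | missingness | covariate effect |
|----|------------------------------|------------------|-------------|------------------|
| 1  | $-1, -1$  | $0.5, 0.5$ | same (30%/30%) | same |
| 2  | $-1, 0.5$ | $0.5, 0.5$ | different (30%/60%) | same |
| 3  | $-1, -1$  | $0.4, 0.6$ | same | different |
| 4  | $-1, 0.5$ | $0.4, 0.6$ | different | different |

The intercepts $-1$ and $0.5$ are the solutions of
$E_X[\mathrm{expit}(-\varphi_0 - X)] = 0.7$ and $0.4$ rounded as used
throughout; `calibrate_phi0()` solves the equation exactly by root-finding on
an adaptive-quadrature evaluation (the exact roots are $-1.018$ and $0.490$;
the study values $-1$ and $0.5$ give observed fractions $0.697$ and
$0.398$).

## Estimators

**Unadjusted cluster-level analysis** (`cl_unadjusted()`): the difference of
arm means of per-cluster means of observed outcomes, tested with the
pooled-variance two-sample t-test on cluster means, df $= k_1 + k_2 - 2$.
Clusters with no observed outcomes have an undefined mean; they are dropped
with a warning and the df shrink accordingly (at the study settings
$P(\text{all } 30 \text{ missing})$ is negligible).

**Adjusted cluster-level analysis** (`cl_adjusted()`): stage one regresses
$Y$ on $X$ by OLS over complete records pooled across arms — deliberately
without the intervention indicator and ignoring clustering, as the two-stage
procedure prescribes; stage two applies the same t-test to cluster means of
the residuals. Under differential selection the pooled slope
$\hat\lambda$ is inconsistent (its probability limit is computed by
`plim_lambda_cra()`), which is exactly why this analysis retains bias in
those conditions.

**Adjusted (design-effect) t-test** (`adjusted_ttest()`): compares raw arm
means of individuals with the variance of each arm mean inflated by
$C_i = 1 + (\bar m_{Ai} - 1)\hat\rho$, using the pooled one-way-ANOVA ICC
estimate after centring each arm at its own mean. The total-variance estimate
is assembled from the same ANOVA components
($\hat\sigma^2 = \hat\sigma_b^2 + \mathrm{MSW}$), which makes the test
*algebraically identical* to the cluster-level t-test on balanced data; a
negative moment estimate of $\sigma_b^2$ is truncated to zero and flagged
(the identity then no longer holds — the degenerate no-clustering case).

**Linear mixed model on complete records** (`fit_lmm_cra()`): REML
random-intercept model via `lme4::lmer`. With `interaction = TRUE` the
covariate enters empirically centred — $X^* = X - \bar X$ with $\bar X$ the
mean over *all* randomised individuals, which is available because $X$ is
fully observed — so the $Z$ coefficient is the average intervention effect at
the mean covariate. The extra variability of $\bar X$ is ignored in the
standard errors; the simulations are the check that this does not hurt
coverage. Confidence intervals use $t$ quantiles with $k_1 + k_2 - 2$ df
rather than normal quantiles, since asymptotic LMM standard errors are
anti-conservative with few clusters.

**Single imputation** (`impute_cluster_mean()`, `impute_group_mean()`):
provided for studying their behaviour. Cluster-mean imputation leaves cluster
means unchanged, so on balanced designs `adjusted_ttest()` after imputation
reproduces the pre-imputation cluster-level t-test exactly; group-mean
imputation strictly shrinks the between-cluster spread of cluster means.

**Multiple imputation** (`mi_impute()` + `mi_analyze()`): a random-effects
imputation model congenial to the analysis model — fixed effects $X$ and $Z$
(plus $X^* Z$ when the analysis model has the interaction), a random
intercept per cluster. Sampling is by a Gibbs sampler over the fixed effects,
cluster intercepts, two variances and the missing outcomes, with an improper
flat prior on fixed effects and inverse-gamma(0.001, 0.001) on both
variances — a standard weakly-informative conjugate choice, made here because
proper conditionals are available in closed form; the posterior is dominated
by the likelihood at the study's sample sizes (parameter-recovery tests
compare the posterior to REML). Initial values come from OLS, with
$\sigma_b^2$ started at the ANOVA moment estimate floored at
$0.01\,\hat\sigma_w^2$ to avoid a degenerate start. Defaults $Q = 20$
imputations after 200 burn-in iterations with 10 iterations between retained
draws; the retained parameter draws are returned in `$trace` for mixing
diagnostics, but convergence is not auto-enforced. Pooling follows Rubin's
rules, and inference uses the Barnard–Rubin adjusted degrees of freedom

$$\nu_{adj} = \left(\frac{1}{\nu} + \frac{1}{\hat\nu_{obs}}\right)^{-1}
 \le \nu_{com}, \qquad
 \nu = (Q-1)\left(1 + \frac{Q\,W}{(Q+1)B}\right)^{2},$$

$$\hat\nu_{obs} = \left(1 + \frac{(Q+1)B}{Q\,W}\right)^{-1}
 \frac{\nu_{com}+1}{\nu_{com}+3}\,\nu_{com},$$

with $\nu_{com} = 2(k-1)$ based on the number of clusters (used regardless of
the interaction term, following the study convention). $B = 0$ is handled as
the limit $\nu \to \infty$, $\nu_{adj} = \hat\nu_{obs}$.

## Analytic bias and variance of the cluster-level estimators

Under the selection model the covariate among observed individuals has the
tilted density $\phi(x)\,\mathrm{expit}(-\varphi_0 - \varphi_1 x)/p_{obs}$.
`selection_moments()` evaluates $p_{obs}$, $\mu_{x|obs}$,
$\mathrm{Var}(X|obs)$ by adaptive quadrature (`stats::integrate`, absolute
tolerance $10^{-10}$; every quadrature output is unit-tested against
brute-force Monte Carlo), and the effective observed cluster size $\eta$ with
$1/\eta = E(1/\sum_l R_{ijl})$ — an exact binomial sum because the $R_{ijl}$
are marginally iid within a cluster, truncated to $\ge 1$ observed outcome
with the $(1 - (1-p)^m)^{-1}$ correction to match the estimator that drops
empty clusters.

On the arm2 − arm1 reporting scale:

$$E(\hat\theta^{obs}) - \theta =
  \beta_2\,\mu_{x21} - \beta_1\,\mu_{x11}, \qquad
  \mathrm{Var}(\hat\theta^{obs}) = \sum_{i=1}^2 \frac{1}{k_i}
  \left(\beta_i^2 \sigma^2_{\bar x i1} + \sigma_b^2 +
  \frac{\sigma_{w,i}^2}{\eta_i}\right),$$

and the adjusted analysis adds $\lambda(\mu_{x11} - \mu_{x21})$ to the bias
and replaces $\beta_i^2$ by $(\beta_i - \lambda)^2$ in the variance. Two
renderings of the variance formula are possible
($\sigma_w^2\,\eta_i$ vs $\sigma_w^2/\eta_i$); the implementation uses
$\sigma_w^2 \cdot E(1/n_{obs}) = \sigma_w^2/\eta_i$, the only reading
consistent with the simulated variance (checked to within 5% over 10,000
replicates). Likewise the individual error variance is taken arm-specific,
$(1 - \tau_i^2 - \rho)\sigma_y^2$, when $\tau_1 \neq \tau_2$.

The bias vanishes iff $\beta_1\mu_{x11} = \beta_2\mu_{x21}$ — in particular
when both arms share the covariate effect *and* the missingness mechanism
(scenario 1) — and with $\beta_i > 0$, $\varphi_{i1} > 0$ the bias is always
downward, because large covariate values (hence large outcomes) are more
likely missing:

```{r theory}
purrr::map(1:4, ~ theory_summary(make_scenario(.x, k = 10, rho = 0.05))) |>
  bind_rows() |>
  select(scenario, lambda_plim, bias_unadj, bias_adj, var_unadj, var_adj)
```

## The simulation harness

`run_cell()` crosses one scenario with a set of methods over `n_reps`
replicates; `run_table()` runs the factorial grid ($k \in \{5,10,20,30\}$,
$\rho \in \{0.001, 0.05, 0.1\}$ by default). A master seed spawns independent
sub-seeds per replicate and stage (outcome draw, missingness draw, imputation
draw), so the generated data are invariant to which methods are requested —
verified by a property test. Replicates where a method fails to converge are
excluded from that method's averages and counted in `n_failures`; a rate
above 1% raises a warning (observed rates at the study settings are well
below 0.5%).

```{r cell}
run_cell(make_scenario(1, k = 10, rho = 0.05),
         methods = c("cl-unadj", "cl-adj", "lmm"),
         n_reps = 100, seed = 2024) |>
  select(method_id, avg_estimate, empirical_sd, avg_se, coverage)
```

Coverage is evaluated against the generative true effect $+5$.
`autoplot()` on a summary draws average estimates with Monte-Carlo error
bars, or empirical coverage, against $k$.

## Numerical and design choices

- **REML engine.** `lme4` fits all mixed models (it is the standard tool for
  exactly this model class); non-convergence is retried with the `bobyqa`
  optimiser and then flagged; singular fits (boundary $\hat\sigma_b^2 = 0$)
  are reported with a flag, not treated as failures. Within `mi_analyze()`
  the $Q$ completed datasets share a design, so fits 2..Q reuse the first
  model structure via `lme4::refit` — numerically equivalent and several
  times faster.
- **Pooled t-test, not Welch.** The cluster-level df convention
  $k_1 + k_2 - 2$ is the pooled-test df, so the pooled-variance (Student)
  test is used throughout.
- **Quadrature.** All selection-model integrals use `stats::integrate` over
  $(-\infty, \infty)$ at tolerance $10^{-10}$; $E(1/n_{obs})$ is an exact
  finite sum, not an integral.
- **Degenerate inputs.** Zero-variance covariate in the first stage, fewer
  than two usable clusters in an arm, unimputable (all-missing) clusters,
  $Q < 2$, and an invalid variance decomposition are all hard errors with
  specific messages; $B = 0$ in pooling and negative ANOVA ICC estimates are
  handled as limits with flags.

## Problem sizes and what the tests show

The packaged checks run the full analytic-method comparisons at 2,000
replicates per cell, MI comparisons at 500 replicates ($Q = 20$), and the
variance cross-check at 10,000 replicates of the cheap cluster-level
estimator — sizes at which a 3-Monte-Carlo-error band around the truth is a
meaningful test (about $\pm 0.08$ on an effect of 5 at 2,000 replicates).
Unit and property tests use smaller sizes sized to the same 3-MC-error logic.

The generator emulates the study conditions exactly: balanced designs, one
standard-normal individual-level covariate, normal random effects, logistic
missingness in that covariate only. Passing tests therefore say nothing
about features real trials add on top — unbalanced cluster sizes (the data
model permits them; the harness does not generate them), non-normal outcomes
or covariates, cluster-level predictors of missingness, missingness
depending on the outcome itself (MNAR), or missing covariates. Within the
emulated conditions the headline findings reproduce: cluster-level analyses
(and cluster-mean imputation) are unbiased only under a shared missingness
mechanism with no covariate-by-intervention interaction; the complete-records
LMM and congenial random-effects MI are unbiased in all four scenarios
provided the interaction is included when present in truth; and MI's
$\nu_{adj} < \nu_{com}$ produces overcoverage when $k$ is small.

## Known limitations

Weighted cluster-level analyses, stratified or pair-matched designs, GEE,
binary outcomes, ABB or non-hierarchical MI variants, and MNAR sensitivity
analyses are out of scope. The Gibbs sampler covers the one-random-intercept
imputation model only, and its priors are fixed (documented above) rather
than user-configurable.
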