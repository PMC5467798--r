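# crtmiss

Missing continuous outcomes in two-arm cluster randomised trials (CRTs) under
**covariate dependent missingness** (CDM): which analyses stay unbiased, and
by how much the others miss.

In a CRT, clusters are randomised but outcomes are measured on individuals,
correlated within clusters (intraclass correlation $\rho$). When the
probability that an outcome $Y$ is missing depends on a fully observed
baseline covariate $X$ — say, older patients skip the follow-up blood-pressure
measurement — complete-records versions of the standard analyses can be
biased. `crtmiss` is for trial statisticians and methodologists who want to
quantify that: it generates trial data from the random-intercept model

$$Y_{ijl} = \alpha_i + \beta_i X_{ijl} + \delta_{ij} + \epsilon_{ijl},
\qquad
\mathrm{logit}\,P(R_{ijl}=0 \mid X_{ijl}) = \varphi_{i0} + \varphi_{i1} X_{ijl},$$

and implements, side by side:

- **unadjusted** and **covariate-adjusted cluster-level analyses**
  (two-stage, pooled-variance t-test on cluster means, df $k_1+k_2-2$);
- the **Donner–Klar adjusted t-test** (design-effect-inflated comparison of
  arm means; identical to the cluster-level t-test on balanced data);
- the **random-intercept linear mixed model** on complete records (REML via
  lme4, t-based intervals with cluster-based df, optional
  intervention-by-centred-covariate interaction);
- **cluster-mean / group-mean single imputation**;
- **random-effects multiple imputation** by a Gibbs sampler, pooled by
  Rubin's rules with **Barnard–Rubin adjusted degrees of freedom**
  $\nu_{adj} = (1/\nu + 1/\hat\nu_{obs})^{-1} \le \nu_{com}$;
- **analytic bias and variance formulas** for the cluster-level estimators
  under the selection model, e.g.
  $E(\hat\theta^{obs}) - \theta = \beta_2\mu_{x21} - \beta_1\mu_{x11}$ and
  $\mathrm{Var}(\hat\theta^{obs}) = \sum_i k_i^{-1}(\beta_i^2\sigma^2_{\bar
  x i1} + \sigma_b^2 + \sigma_{w,i}^2/\eta_i)$, evaluated by quadrature over
  the tilted covariate density;
- a **Monte-Carlo harness** reporting average estimate, empirical and average
  estimated SE, and coverage over factorial (scenario × $k$ × $\rho$) grids.

Everything takes and returns tibbles, pipes cleanly, and has
`tidy()`/`glance()`/`autoplot()` methods. See the vignette
(`vignettes/missing-outcomes-crt.Rmd`) for the model, the four canonical
scenarios, and every numerical choice.

## Worked example

Scenario 4 is the hardest condition: 30% missing in control vs 60% in
intervention, and a covariate effect that differs by arm
($\tau = 0.4$ vs $0.6$). True intervention effect: **5**.

```r
library(crtmiss)
library(dplyr)

scenario <- make_scenario(4, k = 10, rho = 0.05)
trial <- generate_scenario(scenario, seed = 2024)

bind_rows(
  cl_unadjusted(trial),
  cl_adjusted(trial),
  fit_lmm_cra(trial, lmm_spec(interaction = TRUE)),
  mi_analyze(mi_impute(trial, Q = 20, interaction = TRUE, seed = 1))
) |>
  select(method_id, estimate, se, df, ci_low, ci_high, p_value)
#> # A tibble: 4 × 7
#>   method_id estimate    se    df  ci_low ci_high p_value
#>   <chr>        <dbl> <dbl> <dbl>   <dbl>   <dbl>   <dbl>
#> 1 cl-unadj      1.07  1.47  18   -2.02      4.16  0.476
#> 2 cl-adj        2.85  1.39  18   -0.0667    5.77  0.0549
#> 3 lmm           4.00  1.61  18    0.613     7.38  0.0232
#> 4 mi            3.79  1.56  10.9  0.356     7.23  0.0335
```

On this single dataset the cluster-level analyses land far below 5 — their
estimators are biased downward under differential covariate-dependent
selection — while the mixed model and MI (whose pooled df 10.9 is the
Barnard–Rubin $\nu_{adj}$, below $\nu_{com} = 18$) sit near the truth. The
analytic module says how far below, in expectation:

```r
theory_summary(scenario)
#>   scenario  k  rho p_obs_1 p_obs_2 mu_x_obs_1 mu_x_obs_2 lambda_plim bias_unadj
#> 1        4 10 0.05  0.6967   0.398    -0.2554       -0.5       4.434     -1.978
#>   bias_adj var_unadj var_adj
#> 1  -0.8938     2.237   1.926
```

so the unadjusted cluster-level estimate is expected to centre on
$5 - 1.98 = 3.02$ and the adjusted one on $5 - 0.89 = 4.11$ (the first-stage
slope converges to 4.43, not $\beta$). The harness confirms it over
replicates:

```r
run_cell(scenario, methods = c("cl-unadj", "cl-adj", "lmm"),
         n_reps = 2000, seed = 1) |>
  select(method_id, avg_estimate, mc_error_estimate, coverage)
```

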