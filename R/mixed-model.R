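#' Specify the linear mixed model for the intervention-effect analysis
#'
#' The analysis model always has a random intercept per cluster and fixed
#' effects for the baseline covariate and the intervention indicator Z. When
#' `interaction = TRUE` the covariate enters empirically centred
#' (`x* = x - mean(x)` over all randomised individuals, since x is fully
#' observed) together with its interaction with Z, so the Z coefficient is
#' the average intervention effect at the mean covariate value. The extra
#' variability from estimating the centring mean is ignored in the standard
#' errors.
#'
#' @param interaction Include the intervention-by-covariate interaction?
#' @param df Degrees of freedom for the Wald t inference; default
#'   `k1 + k2 - 2`, resolved at fit time.
#' @return A list of class `crt_lmm_spec`.
#' @export
lmm_spec <- function(interaction = FALSE, df = NULL) {
  structure(list(interaction = isTRUE(interaction), df = df),
            class = "crt_lmm_spec")
}

#' Analysis-model choice for each canonical scenario
#'
#' The interaction between intervention and covariate is included exactly
#' when the data-generating model has differing covariate effects between
#' arms: scenarios 3 and 4.
#'
#' @param id Scenario identifier, 1 to 4.
#' @return An [lmm_spec()].
#' @examples
#' choose_model_for_scenario(3)$interaction
#' @export
choose_model_for_scenario <- function(id) {
  if (length(id) != 1 || !id %in% 1:4) {
    stop("unknown scenario id: must be 1, 2, 3 or 4", call. = FALSE)
  }
  lmm_spec(interaction = id %in% c(3, 4))
}

# Build the model frame used by both the analysis LMM and the MI engine:
# intervention indicator z, global cluster key, centred covariate.
lmm_frame <- function(data) {
  data <- check_crt_data(data)
  dplyr::mutate(data,
                z = as.numeric(.data$arm == 2),
                cl_id = paste(.data$arm, .data$cluster, sep = ":"),
                xc = .data$x - mean(.data$x))
}

#' Random-intercept linear mixed model on complete records
#'
#' Fits, by REML (via [lme4::lmer()]), the model
#' `y ~ x + z + (1 | cluster)` — or `y ~ x* + z + x*:z + (1 | cluster)` with
#' the empirically centred covariate when the spec requests the interaction —
#' to the records with observed outcomes. Inference for the Z coefficient
#' uses a t distribution with `k1 + k2 - 2` degrees of freedom, since the
#' asymptotic (normal) intervals are anti-conservative with few clusters.
#'
#' Non-convergence is retried with the bobyqa optimiser; if that also fails
#' the result carries a `"nonconvergence"` flag and `NA` estimates. A
#' singular fit (between-cluster variance at the zero boundary) is flagged
#' but reported.
#'
#' @param data A CRT dataset tibble (only `r == 1` records are used).
#' @param spec An [lmm_spec()].
#' @param ci_level Confidence level.
#' @return A one-row `crt_result` tibble with the Z-coefficient inference;
#'   the lme4 fit is attached as attribute `fit` and the estimated variance
#'   components as attribute `varcomp` (`sigma_b2`, `sigma_w2`).
#' @examples
#' d <- generate_scenario(make_scenario(1, k = 5), seed = 1)
#' fit_lmm_cra(d, lmm_spec(interaction = FALSE))
#' @export
fit_lmm_cra <- function(data, spec = lmm_spec(), ci_level = 0.95) {
  stopifnot(inherits(spec, "crt_lmm_spec"))
  df <- lmm_frame(data)
  obs <- dplyr::filter(df, .data$r == 1)
  k_used <- dplyr::n_distinct(obs$cl_id[obs$arm == 1]) +
    dplyr::n_distinct(obs$cl_id[obs$arm == 2])
  form <- if (spec$interaction) y ~ xc * z + (1 | cl_id) else y ~ x + z + (1 | cl_id)
  fit <- fit_lmer_robust(form, obs)
  dof <- if (is.null(spec$df)) k_used - 2 else spec$df
  if (is.null(fit$fit)) {
    res <- tibble::tibble(method_id = "lmm", estimate = NA_real_, se = NA_real_,
                          df = dof, ci_low = NA_real_, ci_high = NA_real_,
                          p_value = NA_real_, warnings = list(fit$warnings))
    class(res) <- c("crt_result", class(res))
    return(res)
  }
  b <- lme4::fixef(fit$fit)
  V <- as.matrix(stats::vcov(fit$fit))
  est <- unname(b[["z"]])
  se <- sqrt(V["z", "z"])
  res <- new_method_result("lmm", est, se, dof, ci_level, fit$warnings)
  vc <- lme4::VarCorr(fit$fit)
  attr(res, "fit") <- fit$fit
  attr(res, "varcomp") <- c(sigma_b2 = unname(vc$cl_id[1, 1]),
                            sigma_w2 = attr(vc, "sc")^2)
  res
}

# REML fit with a quiet default attempt, a bobyqa retry on convergence
# warnings, and singularity flagged. Returns list(fit or NULL, warnings).
fit_lmer_robust <- function(form, data) {
  warns <- character()
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  fit <- tryCatch(
    withCallingHandlers(
      lme4::lmer(form, data = data, REML = TRUE, control = ctrl),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w)); invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(fit) || length(warns)) {
    ctrl2 <- lme4::lmerControl(optimizer = "bobyqa",
                               check.conv.singular = "ignore")
    warns2 <- character()
    fit2 <- tryCatch(
      withCallingHandlers(
        lme4::lmer(form, data = data, REML = TRUE, control = ctrl2),
        warning = function(w) {
          warns2 <<- c(warns2, conditionMessage(w)); invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (!is.null(fit2) && !length(warns2)) {
      fit <- fit2
      warns <- character()
    } else if (is.null(fit)) {
      return(list(fit = NULL, warnings = c("nonconvergence", warns, warns2)))
    } else {
      warns <- c("nonconvergence", warns)
    }
  }
  if (!is.null(fit) && lme4::isSingular(fit)) {
    warns <- c(warns, "singular fit: between-cluster variance at boundary")
  }
  list(fit = fit, warnings = warns)
}
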