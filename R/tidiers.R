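#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a method result
#'
#' Returns the one-row result tibble with plain classes, in broom's
#' `term`/`estimate` idiom for the intervention effect.
#'
#' @param x A `crt_result`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `df`, `p.value`, `conf.low`, `conf.high`.
#' @export
tidy.crt_result <- function(x, ...) {
  tibble::tibble(term = "intervention", estimate = x$estimate,
                 std.error = x$se, statistic = x$estimate / x$se,
                 df = x$df, p.value = x$p_value,
                 conf.low = x$ci_low, conf.high = x$ci_high)
}

#' @rdname tidy.crt_result
#' @export
glance.crt_result <- function(x, ...) {
  tibble::tibble(method_id = x$method_id, df = x$df,
                 n_warnings = length(x$warnings[[1]]))
}

#' Tidy pooled multiple-imputation output
#'
#' @param x A `crt_mi_pooled`.
#' @param ... Unused.
#' @return A one-row tibble with the pooled estimate and its inference.
#' @export
tidy.crt_mi_pooled <- function(x, ...) {
  tibble::tibble(term = "intervention", estimate = x$qbar,
                 std.error = sqrt(x$total_var), df = x$nu_adj,
                 p.value = x$p_value, conf.low = x$ci_low, conf.high = x$ci_high)
}

#' @rdname tidy.crt_mi_pooled
#' @export
glance.crt_mi_pooled <- function(x, ...) {
  tibble::tibble(Q = x$Q, W = x$W, B = x$B, total_var = x$total_var,
                 nu = x$nu, nu_obs = x$nu_obs, nu_adj = x$nu_adj,
                 nu_com = x$nu_com)
}

#' Plot a simulation summary
#'
#' Average intervention-effect estimate per method with 95% Monte-Carlo
#' error bars, faceted over the intraclass correlation, against the number
#' of clusters per arm; the dashed line marks the true effect. Coverage can
#' be plotted instead with `metric = "coverage"`.
#'
#' @param object A `crt_sim_summary` from [run_cell()] or [run_table()].
#' @param metric `"estimate"` or `"coverage"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crt_sim_summary <- function(object, metric = c("estimate", "coverage"),
                                     ...) {
  metric <- match.arg(metric)
  df <- tibble::as_tibble(object)
  if (metric == "estimate") {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$avg_estimate,
                                          colour = .data$method_id)) +
      ggplot2::geom_hline(ggplot2::aes(yintercept = .data$true_effect),
                          linetype = "dashed", colour = "grey40") +
      ggplot2::geom_pointrange(ggplot2::aes(
        ymin = .data$avg_estimate - 1.96 * .data$mc_error_estimate,
        ymax = .data$avg_estimate + 1.96 * .data$mc_error_estimate),
        position = ggplot2::position_dodge(width = 1)) +
      ggplot2::labs(y = "average estimate", x = "clusters per arm",
                    colour = "method")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$coverage,
                                          colour = .data$method_id)) +
      ggplot2::geom_hline(yintercept = 0.95, linetype = "dashed",
                          colour = "grey40") +
      ggplot2::geom_point(position = ggplot2::position_dodge(width = 1)) +
      ggplot2::labs(y = "empirical coverage", x = "clusters per arm",
                    colour = "method")
  }
  if (dplyr::n_distinct(df$rho) > 1) {
    p <- p + ggplot2::facet_wrap(~rho, labeller = ggplot2::label_both)
  }
  p + ggplot2::theme_minimal()
}
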