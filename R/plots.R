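#' Forest-style plot of prevalence estimates
#'
#' @param estimates Output of [substance_prevalence()],
#'   [class_prevalence()] or [sample_status_rates()].
#' @return A ggplot object: point estimates with CI bars.
#' @export
plot_prevalence <- function(estimates) {
  pct_col <- if ("prevalence_pct" %in% names(estimates)) "prevalence_pct" else "share_pct"
  estimates |>
    dplyr::mutate(label = stats::reorder(.data$label, .data[[pct_col]])) |>
    ggplot2::ggplot(ggplot2::aes(x = .data[[pct_col]], y = .data$label)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low_pct,
                                          xmax = .data$ci_high_pct)) +
    ggplot2::labs(x = "Positive samples, % (with CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a recovery experiment
#'
#' Replicate estimates per estimator, with the generative truth as a
#' dashed line; the gap between the adjusted and naive boxes visualises
#' what carryover does to an unadjusted analysis.
#'
#' @param object A `recovery_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot recovery_experiment
#' @export
autoplot.recovery_experiment <- function(object, ...) {
  ggplot2::ggplot(object$replicates,
                  ggplot2::aes(x = .data$estimator, y = .data$estimate_pct)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = object$true_pct, linetype = "dashed") +
    ggplot2::labs(
      x = NULL, y = "Estimated prevalence, %",
      title = paste0(object$substance, ": ", object$n_replicates,
                     " simulated studies"),
      subtitle = sprintf("dashed line: true use prevalence %.1f%%",
                         object$true_pct)
    ) +
    ggplot2::theme_minimal()
}
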