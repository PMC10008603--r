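#' Plot per-fold metrics of one evaluation
#'
#' Dot-and-summary plot of the four metrics across cross-validation folds.
#'
#' @param object An `eval_result` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.eval_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$folds,
                              dplyr::all_of(c("acc", "pre", "sn", "f1")),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "firebrick") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      title = paste0(object$spec$kind, ", ", object$n_folds, "-fold CV"),
      x = NULL, y = "metric value"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the stability trend of an ablation
#'
#' Across-combination standard deviation of the mean f1 per arity, one line
#' per feature kind and classifier: the downward trend with growing arity
#' is the stability gain from fusing more modalities.
#'
#' @param object An `ablation_report` from [run_ablation()].
#' @param metric Metric to display, default `"f1"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ablation_report <- function(object, metric = "f1", ...) {
  agg <- aggregate_by_arity(object)
  sd_col <- paste0(metric, "_sd")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$arity, y = .data[[sd_col]],
                                    colour = .data$classifier,
                                    linetype = .data$feature_kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = sort(unique(agg$arity))) +
    ggplot2::labs(
      title = "Across-combination stability by arity",
      x = "modalities fused (arity)",
      y = paste0("sd of mean ", metric, " across combinations")
    ) +
    ggplot2::theme_minimal()
}
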