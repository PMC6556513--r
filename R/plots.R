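#' Plot methods for result objects
#'
#' `autoplot.bootstrap_cv()` shows the bootstrap distribution of each
#' performance metric; `autoplot.selection_trace()` the cumulative mean AUC
#' as features are added (the chosen size marked); `autoplot.rct_result()`
#' the achieved-power and mean odds-ratio curves against enrolment size.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name result-plots
NULL

#' @rdname result-plots
#' @method autoplot bootstrap_cv
#' @export
autoplot.bootstrap_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$iterations, -"iteration",
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(
      x = "held-out value", y = "iterations",
      title = sprintf(
        "Bootstrap CV metric distributions (%s, %d iterations)",
        object$spec$kind, object$n_iter
      )
    )
}

#' @rdname result-plots
#' @method autoplot selection_trace
#' @export
autoplot.selection_trace <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$step, y = .data$auc_mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      fill = "steelblue", alpha = 0.25
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(
      xintercept = object$chosen_size,
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(
      x = "features in model", y = "mean out-of-fold AUC",
      title = "Greedy forward feature selection"
    )
}

#' @rdname result-plots
#' @method autoplot rct_result
#' @export
autoplot.rct_result <- function(object, ...) {
  d <- tibble::as_tibble(object)
  long <- dplyr::bind_rows(
    tibble::tibble(
      n = d$n, quantity = "achieved power", value = d$power,
      ci_low = d$power_ci_low, ci_high = d$power_ci_high
    ),
    tibble::tibble(
      n = d$n, quantity = "mean odds ratio", value = d$or_mean,
      ci_low = d$or_ci_low, ci_high = d$or_ci_high
    )
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$value)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      fill = "firebrick", alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(
      x = "patients enrolled (N)", y = NULL,
      title = sprintf(
        "Simulated RCTs (%d repetitions per N, alpha = %g)",
        attr(object, "n_rep"), attr(object, "alpha")
      )
    )
}

#' Bar chart of the model-comparison table
#'
#' Plots one bar per predictor set and classifier for a chosen metric, with
#' its bootstrap confidence interval, mirroring the usual low- vs
#' high-dimensional comparison figure.
#'
#' @param performance The `performance` tibble of an [run_experiment()]
#'   result.
#' @param metric Which metric to show.
#' @return A ggplot object.
#' @export
plot_performance <- function(performance, metric = "auc") {
  d <- dplyr::filter(performance, .data$metric == !!metric)
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = stats::reorder(.data$predictor_set, .data$mean),
      y = .data$mean, fill = .data$classifier
    )
  ) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(0.8), width = 0.25
    ) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste("mean", metric), fill = "classifier")
}
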