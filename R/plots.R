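# Report-style figures: prediction traces, scatter against the identity
# line, error histograms, PSO convergence, and explanation bars.

#' @importFrom rlang .data
NULL

#' Actual vs predicted dose by sample index
#'
#' @param bench a `bench_result`.
#' @param family family name to plot.
#' @return a ggplot object.
#' @export
plot_predictions <- function(bench, family) {
  f <- bench$fits[[family]]
  if (is.null(f)) stop("no fitted results for family '", family, "'", call. = FALSE)
  df <- data.frame(index = seq_along(f$y_true),
                   value = c(f$y_true, f$predictions),
                   series = rep(c("actual", "predicted"),
                                each = length(f$y_true)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "test sample", y = "breast dose (mGy)",
                  title = family, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Predicted vs actual scatter with the identity line
#'
#' @inheritParams plot_predictions
#' @return a ggplot object.
#' @export
plot_pred_scatter <- function(bench, family) {
  f <- bench$fits[[family]]
  if (is.null(f)) stop("no fitted results for family '", family, "'", call. = FALSE)
  df <- data.frame(actual = f$y_true, predicted = f$predictions)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$actual, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red",
                         linetype = "dashed") +
    ggplot2::labs(x = "actual dose (mGy)", y = "predicted dose (mGy)",
                  title = family) +
    ggplot2::theme_minimal()
}

#' Prediction-error histogram
#'
#' @inheritParams plot_predictions
#' @return a ggplot object.
#' @export
plot_error_hist <- function(bench, family) {
  f <- bench$fits[[family]]
  if (is.null(f)) stop("no fitted results for family '", family, "'", call. = FALSE)
  df <- data.frame(error = f$y_true - f$predictions)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$error)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = "actual - predicted (mGy)", y = "count",
                  title = family) +
    ggplot2::theme_minimal()
}

#' PSO convergence plot (per-particle p_best and global g_best)
#'
#' @param trace a `pso_trace`.
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_pso_trace <- function(trace, title = "PSO convergence") {
  stopifnot(inherits(trace, "pso_trace"))
  it <- seq_len(nrow(trace$p_best)) - 1
  pb <- data.frame(
    iteration = rep(it, ncol(trace$p_best)),
    score = as.vector(trace$p_best),
    particle = factor(rep(seq_len(ncol(trace$p_best)), each = length(it)))
  )
  gb <- data.frame(iteration = it, score = trace$g_best)
  ggplot2::ggplot(pb, ggplot2::aes(x = .data$iteration, y = .data$score,
                                   group = .data$particle)) +
    ggplot2::geom_line(alpha = 0.35, colour = "grey40") +
    ggplot2::geom_line(data = gb, ggplot2::aes(group = NULL),
                       colour = "red", linewidth = 0.8) +
    ggplot2::labs(x = "iteration", y = "objective (CV MSE)", title = title) +
    ggplot2::theme_minimal()
}

#' Horizontal-bar plot of a local explanation
#'
#' @param explanation an `explanation` object.
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_explanation <- function(explanation, title = "Local explanation") {
  stopifnot(inherits(explanation, "explanation"))
  df <- explanation$features
  df$condition <- factor(df$condition,
                         levels = rev(df$condition[order(abs(df$contribution))]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$contribution, y = .data$condition,
                                   fill = .data$contribution > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "forestgreen",
                                          `FALSE` = "firebrick")) +
    ggplot2::labs(x = "contribution to prediction (mGy)", y = NULL,
                  title = title) +
    ggplot2::theme_minimal()
}
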