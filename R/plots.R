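# ggplot2 visualizations for the main result types.

#' Plot an inference result
#'
#' For EM methods, the penalized log-likelihood trace across iterations;
#' for majority vote, the distribution of maximum posterior (vote share).
#'
#' @param object A `crowd_inference`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crowd_inference <- function(object, ...) {
  if (length(object$loglik_trace) > 0L) {
    df <- tibble::tibble(iteration = seq_along(object$loglik_trace),
                         loglik = object$loglik_trace)
    ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$loglik)) +
      ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
      ggplot2::labs(title = sprintf("%s convergence", object$method),
                    x = "EM iteration", y = "penalized log-likelihood") +
      ggplot2::theme_minimal()
  } else {
    df <- tibble::tibble(confidence = apply(object$posteriors, 1, max))
    ggplot2::ggplot(df, ggplot2::aes(.data$confidence)) +
      ggplot2::geom_histogram(bins = 20) +
      ggplot2::labs(title = "Majority-vote confidence",
                    x = "top vote share", y = "tasks") +
      ggplot2::theme_minimal()
  }
}

#' Plot an active-learning curve
#'
#' Held-out accuracy and macro-F1 against query iteration.
#'
#' @param object An `al_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.al_run <- function(object, ...) {
  df <- tidyr::pivot_longer(object$curve[c("iteration", "accuracy",
                                           "macro_f1")],
                            c("accuracy", "macro_f1"),
                            names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = sprintf("Active learning (%s, %s sampling)",
                                  object$family, object$strategy),
                  x = "iteration", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a local Shapley attribution
#'
#' Signed contribution of each feature group to one prediction.
#'
#' @param object A `shapley` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shapley <- function(object, ...) {
  df <- dplyr::arrange(object$phi, abs(.data$phi))
  df$group <- factor(df$group, levels = df$group)
  ggplot2::ggplot(df, ggplot2::aes(.data$phi, .data$group,
                                   fill = .data$phi > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(title = sprintf("f(x) = %.3f, base = %.3f",
                                  object$fx, object$base_value),
                  x = "Shapley value", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot worker activity volumes
#'
#' Histogram of completed HITs per worker (log-scaled counts), the classic
#' heavy-tailed crowd-work pattern.
#'
#' @param assignments Assignment records tibble.
#' @return A ggplot object.
#' @export
plot_worker_activity <- function(assignments) {
  df <- assignments %>%
    dplyr::distinct(.data$hit_id, .data$worker_id) %>%
    dplyr::count(.data$worker_id, name = "hits")
  ggplot2::ggplot(df, ggplot2::aes(.data$hits)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "HITs completed (log scale)", y = "workers") +
    ggplot2::theme_minimal()
}

#' Plot global feature importance
#'
#' @param importance Tibble from [global_importance()].
#' @param top_n Show the top `top_n` groups.
#' @return A ggplot object.
#' @export
plot_importance <- function(importance, top_n = 12L) {
  df <- utils::head(importance, top_n)
  df$group <- factor(df$group, levels = rev(df$group))
  ggplot2::ggplot(df, ggplot2::aes(.data$importance, .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "global importance (sum of |phi|)", y = NULL) +
    ggplot2::theme_minimal()
}
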