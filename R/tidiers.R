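#' Tidy per-fold metrics of an evaluation
#'
#' @param x A `vigi_eval` from [nested_cv_evaluate()].
#' @param ... Unused.
#' @return Tibble of per-outer-fold metrics.
#' @export
tidy.vigi_eval <- function(x, ...) {
  x$per_fold
}

#' One-row pooled summary of an evaluation
#'
#' @param x A `vigi_eval`.
#' @param ... Unused.
#' @return One-row tibble: pooled metrics plus condition, period, trial
#'   counts and the all-positive baseline.
#' @export
glance.vigi_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(condition = x$condition, period = x$period %||% NA_character_,
                   window_s = x$window_s %||% NA_real_,
                   n_incorrect = x$n_incorrect, n_correct = x$n_correct,
                   baseline_f1 = x$baseline_f1),
    x$pooled
  )
}

#' Selection-curve plot for an evaluation
#'
#' Training (inner-CV) F1 versus the number of wrapper-selected features,
#' one line per outer fold, with the all-positive baseline as a dashed
#' reference.
#'
#' @param object A `vigi_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vigi_eval <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$step, y = .data$f1,
                               group = .data$fold,
                               colour = factor(.data$fold))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = object$baseline_f1,
                        linetype = "dashed") +
    ggplot2::labs(x = "number of selected features",
                  y = "inner-CV F1 (training folds)",
                  colour = "outer fold",
                  title = sprintf("Wrapper selection curve (%s, %s)",
                                  object$condition,
                                  object$period %||% "")) +
    ggplot2::theme_minimal()
}

#' Per-channel performance plot
#'
#' @param x Output of [single_channel_evaluation()].
#' @return A ggplot object (bar chart with the all-positive baseline).
#' @export
plot_channel_f1 <- function(x) {
  ggplot2::ggplot(x, ggplot2::aes(x = factor(.data$channel,
                                             levels = .data$channel),
                                  y = .data$f1)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_hline(yintercept = attr(x, "baseline_f1"),
                        linetype = "dashed") +
    ggplot2::labs(x = "channel", y = "pooled F1") +
    ggplot2::theme_minimal()
}

#' Feature-distribution plot for the top discriminative features
#'
#' Shows the per-class distribution of the `n_top` features with the
#' highest point-biserial R^2, the view used to inspect class
#' separability.
#'
#' @param features Feature table from [extract_features()].
#' @param n_top Number of features to show (default 2).
#' @return A ggplot object.
#' @export
plot_feature_separation <- function(features, n_top = 2) {
  top <- utils::head(feature_r2(features), n_top)
  long <- tidyr::pivot_longer(
    features[, c("outcome", top$column)],
    cols = -"outcome", names_to = "feature", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, fill = .data$outcome)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::facet_wrap(~ .data$feature, scales = "free") +
    ggplot2::theme_minimal()
}
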