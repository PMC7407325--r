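# ggplot2 autoplot() methods. Figures are a thin layer over the tidy
# tables; the pipeline itself only writes data files.

#' Plot a consensus agreement-threshold curve
#'
#' Precision, sensitivity, specificity and FDR against the agreement
#' threshold k (subjects selected by at least k models), the standard
#' consensus diagnostic of the ensemble.
#'
#' @param object A `consensus_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot consensus_curve
autoplot.consensus_curve <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("precision", "sensitivity", "specificity", "fdr"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(df$k)) +
    ggplot2::labs(x = "agreement threshold k (models selecting)",
                  y = "rate", colour = NULL,
                  title = "Consensus segment metrics") +
    ggplot2::theme_minimal()
}

#' Plot a permutation null distribution
#'
#' Histogram of the shuffled-label null statistics with the observed
#' statistic marked.
#'
#' @param object A `permutation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot permutation_result
autoplot.permutation_result <- function(object, ...) {
  df <- tibble::tibble(stat = object$null_statistics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red",
                        linetype = 2) +
    ggplot2::labs(
      x = sprintf("null %s", object$statistic), y = "count",
      title = sprintf("Label-shuffle test: p = %.3g (%d reps)",
                      object$p_value, object$n_reps)
    ) +
    ggplot2::theme_minimal()
}

#' Heat map of a symptom-correlation (difference) matrix
#'
#' @param object A `symptom_cor` or `symptom_cor_diff`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot symptom_cor
autoplot.symptom_cor <- function(object, ...) {
  df <- tidy(object)
  val <- names(df)[3]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$symptom,
                                   fill = .data[[val]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1,
                                                       vjust = 0.5))
}

#' @rdname autoplot.symptom_cor
#' @export
#' @method autoplot symptom_cor_diff
autoplot.symptom_cor_diff <- function(object, ...) {
  autoplot.symptom_cor(object, ...)
}

#' Random-forest importance profile of a build
#'
#' Ranked feature importances with per-tree standard-error bars for the
#' final iteration of an iterative bucket build.
#'
#' @param object A `bucket_build`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot bucket_build
autoplot.bucket_build <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::arrange(dplyr::desc(.data$rf_importance)) |>
    dplyr::mutate(feature = factor(.data$feature, levels = .data$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$feature,
                                   y = .data$rf_importance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$rf_importance - .data$rf_se,
      ymax = .data$rf_importance + .data$rf_se
    ), width = 0.3) +
    ggplot2::labs(x = NULL, y = "random-forest importance (impurity)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1,
                                                       vjust = 0.5))
}
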