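# broom-style tidy()/glance() methods for the package's result objects.

#' Tidy a fitted bucket of models
#'
#' One row per model with its held-out accuracy and failure flag.
#'
#' @param x A `bucket_result`.
#' @param ... Unused.
#' @return Tibble: `model`, `label`, `accuracy`, `failed`.
#' @export
#' @method tidy bucket_result
tidy.bucket_result <- function(x, ...) {
  x$models
}

#' @rdname tidy.bucket_result
#' @export
#' @method glance bucket_result
glance.bucket_result <- function(x, ...) {
  ok <- !x$models$failed & !is.na(x$models$accuracy)
  s <- accuracy_summary(x$models$accuracy[ok])
  tibble::tibble(
    n_models = nrow(x$models),
    n_failed = sum(x$models$failed),
    n_features = length(x$features_used),
    mean_accuracy = s$mean,
    sd_accuracy = s$sd,
    min_accuracy = min(x$models$accuracy[ok])
  )
}

#' Tidy an iterative bucket build
#'
#' The final feature set with its random-forest importance (+- standard
#' error) and the linear-SVM and logistic coefficients, the layout of the
#' final-model region table.
#'
#' @param x A `bucket_build`.
#' @param ... Unused.
#' @return Tibble: `feature`, `rf_importance`, `rf_se`, `svm`, `logistic`,
#'   `day`.
#' @export
#' @method tidy bucket_build
tidy.bucket_build <- function(x, ...) {
  imp <- x$result$importance
  out <- dplyr::left_join(imp, x$result$coefficients, by = "feature")
  names(out)[names(out) == "importance"] <- "rf_importance"
  names(out)[names(out) == "se"] <- "rf_se"
  out
}

#' @rdname tidy.bucket_build
#' @export
#' @method glance bucket_build
glance.bucket_build <- function(x, ...) {
  tibble::tibble(
    iterations = nrow(x$log),
    n_features_initial = x$log$n_features[1],
    n_features_final = length(x$final_features),
    converged = x$converged,
    stop_reason = x$stop_reason,
    min_floor_accuracy = min(x$floor_accuracy, na.rm = TRUE)
  )
}

#' Tidy a consensus curve
#'
#' @param x A `consensus_curve`.
#' @param ... Unused.
#' @return The per-threshold segment tibble (`k`, `n_selected`, counts and
#'   rates).
#' @export
#' @method tidy consensus_curve
tidy.consensus_curve <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("k", "n_selected", "true_positives",
                                 "false_positives", "precision",
                                 "sensitivity", "specificity", "fdr")])
}

#' @rdname tidy.consensus_curve
#' @export
#' @method glance consensus_curve
glance.consensus_curve <- function(x, ...) {
  tibble::tibble(
    n_models = attr(x, "n_models"),
    mean_accuracy = attr(x, "mean_accuracy"),
    sd_accuracy = attr(x, "sd_accuracy"),
    precision_k1 = x$precision[x$k == 1],
    precision_kM = x$precision[x$k == attr(x, "n_models")]
  )
}

#' Tidy a permutation test result
#'
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @return Tibble of per-model observed accuracies and permutation
#'   p-values.
#' @export
#' @method tidy permutation_result
tidy.permutation_result <- function(x, ...) {
  x$per_model
}

#' @rdname tidy.permutation_result
#' @export
#' @method glance permutation_result
glance.permutation_result <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    observed = x$observed,
    p_value = x$p_value,
    n_reps = x$n_reps,
    bonferroni_alpha = x$bonferroni_alpha
  )
}

#' Tidy a symptom-correlation matrix (long format)
#'
#' @param x A `symptom_cor` or `symptom_cor_diff` matrix.
#' @param ... Unused.
#' @return Tibble: `symptom`, `region`, `r`.
#' @export
#' @method tidy symptom_cor
tidy.symptom_cor <- function(x, ...) {
  m <- unclass(x)
  attr(m, "group") <- NULL
  attr(m, "constant_cells") <- NULL
  tibble::tibble(
    symptom = rep(rownames(m), times = ncol(m)),
    region = rep(colnames(m), each = nrow(m)),
    r = as.vector(m)
  )
}

#' @rdname tidy.symptom_cor
#' @export
#' @method tidy symptom_cor_diff
tidy.symptom_cor_diff <- function(x, ...) {
  out <- tidy.symptom_cor(x, ...)
  names(out)[names(out) == "r"] <- "r_diff"
  out
}
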