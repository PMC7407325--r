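#' Per-subject agreement counts across models
#'
#' For each test subject, the number of models predicting the positive
#' class. Failed models (rows of `NA`) are excluded.
#'
#' @param predictions Models x subjects logical matrix (`TRUE` = positive
#'   prediction), e.g. `bucket_result$predictions`.
#' @return Integer vector of length `ncol(predictions)`, range 0..M.
#' @export
agreement_counts <- function(predictions) {
  stopifnot(is.matrix(predictions))
  keep <- rowSums(is.na(predictions)) == 0
  counts <- colSums(predictions[keep, , drop = FALSE])
  storage.mode(counts) <- "integer"
  counts
}

#' Metrics of one consensus segment
#'
#' The segment at agreement threshold `k` selects the subjects predicted
#' positive by at least `k` models. Precision is the fraction of selected
#' subjects truly positive (reported `NA` when nothing is selected),
#' sensitivity the selected true positives over all positives, FDR the
#' complement of precision, and specificity one minus the false positives
#' over all negatives.
#'
#' @param counts Per-subject agreement counts (from [agreement_counts()]).
#' @param labels Logical vector (`TRUE` = positive) or factor whose second
#'   level is the positive class.
#' @param k Agreement threshold, `1 <= k <= M`.
#' @param n_models Number of models M (defaults to `max(counts)`).
#' @return One-row tibble: `k`, `n_selected`, `true_positives`,
#'   `false_positives`, `precision`, `sensitivity`, `specificity`, `fdr`.
#' @export
#' @examples
#' segment_metrics(c(3, 1, 2, 0, 0), c(TRUE, TRUE, FALSE, FALSE, FALSE),
#'                 k = 2, n_models = 3)
segment_metrics <- function(counts, labels, k, n_models = max(counts)) {
  if (is.factor(labels)) {
    labels <- labels == levels(labels)[2L]
  }
  stopifnot(length(counts) == length(labels), k >= 1, k <= n_models)
  sel <- counts >= k
  tp <- sum(sel & labels)
  fp <- sum(sel & !labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  tibble::tibble(
    k = as.integer(k),
    n_selected = sum(sel),
    true_positives = tp,
    false_positives = fp,
    precision = if (sum(sel) > 0) tp / sum(sel) else NA_real_,
    sensitivity = if (n_pos > 0) tp / n_pos else NA_real_,
    specificity = if (n_neg > 0) 1 - fp / n_neg else NA_real_,
    fdr = if (sum(sel) > 0) fp / sum(sel) else NA_real_
  )
}

#' Consensus agreement-threshold curve of a fitted bucket
#'
#' One [segment_metrics()] row per agreement threshold k = 1..M over the
#' bucket's test-set predictions, plus the per-model accuracies and their
#' mean with population standard deviation (the arithmetic used for the
#' reported "mean ± SD" model accuracy summaries).
#'
#' @param bucket A `bucket_result` (or `bucket_build`).
#' @param labels Optional test labels; defaults to those stored in the
#'   result.
#' @return An object of class `consensus_curve`: tibble of segment rows
#'   with attributes `model_accuracies`, `mean_accuracy`, `sd_accuracy`
#'   (population SD) and `n_models`.
#' @export
consensus_curve <- function(bucket, labels = NULL) {
  if (inherits(bucket, "bucket_build")) {
    bucket <- bucket$result
  }
  stopifnot(inherits(bucket, "bucket_result"))
  ok <- !bucket$models$failed
  if (!any(ok)) {
    stop("no non-failed model in the bucket", call. = FALSE)
  }
  labels <- labels %||% (bucket$test_y == bucket$positive_class)
  if (is.factor(labels)) {
    labels <- labels == levels(labels)[2L]
  }
  pred <- bucket$predictions[ok, , drop = FALSE]
  m <- nrow(pred)
  counts <- agreement_counts(pred)
  rows <- purrr::map_dfr(seq_len(m), function(k) {
    segment_metrics(counts, labels, k, n_models = m)
  })
  accs <- bucket$models$accuracy[ok]
  structure(
    rows,
    model_accuracies = setNames(accs, bucket$models$model[ok]),
    mean_accuracy = mean(accs),
    sd_accuracy = sqrt(mean((accs - mean(accs))^2)),
    n_models = m,
    class = c("consensus_curve", class(rows))
  )
}

#' @export
print.consensus_curve <- function(x, ...) {
  cat(sprintf(
    "<consensus_curve> %d models, mean accuracy %.0f%% +/- %.0f%% (population SD)\n",
    attr(x, "n_models"), 100 * attr(x, "mean_accuracy"),
    100 * attr(x, "sd_accuracy")
  ))
  NextMethod()
}

#' Mean and population SD of per-model accuracies
#'
#' The summary arithmetic behind the reported "average ± SD" accuracy rows:
#' an arithmetic mean across models and a *population* (divide-by-M)
#' standard deviation.
#'
#' @param accuracies Numeric vector of per-model accuracies.
#' @return Tibble with `mean` and `sd`.
#' @export
#' @examples
#' accuracy_summary(c(70, 70, 82, 77, 69, 74, 73, 82, 76))
accuracy_summary <- function(accuracies) {
  accuracies <- accuracies[!is.na(accuracies)]
  tibble::tibble(
    mean = mean(accuracies),
    sd = sqrt(mean((accuracies - mean(accuracies))^2))
  )
}

#' Full-pipeline label-shuffle permutation test
#'
#' Re-runs the entire iterative bucket build on uniformly re-shuffled group
#' labels `n_reps` times and compares a summary statistic of the observed
#' build against the null distribution. The default statistic is the
#' minimum per-model final accuracy (every model must beat its null);
#' `"mean_accuracy"` is available by configuration. P-values use the
#' add-one rule, p = (1 + #\{null >= observed\}) / (n_reps + 1); per-model
#' p-values are computed the same way from each model's accuracy, and the
#' Bonferroni-adjusted alpha (0.05 / M) is reported alongside.
#'
#' @param data Cohort table with `group` plus region columns.
#' @param config A [bucket_config()].
#' @param n_reps Number of label permutations (default 200; the reference
#'   protocol used 1000).
#' @param seed Integer seed.
#' @param statistic `"min_accuracy"` (default) or `"mean_accuracy"`.
#' @param regions Feature columns.
#' @param observed Optional pre-computed `bucket_build` for the unshuffled
#'   data (saves one build).
#' @return An object of class `permutation_result`: observed statistic,
#'   null statistics, `p_value`, per-model tibble with p-values,
#'   `bonferroni_alpha`, `n_reps`.
#' @export
shuffle_test <- function(data, config = bucket_config(), n_reps = 200L,
                         seed = 1L, statistic = c("min_accuracy",
                                                  "mean_accuracy"),
                         regions = region_cols(data), observed = NULL) {
  statistic <- match.arg(statistic)
  stopifnot(n_reps >= 1)
  stat_fun <- function(build) {
    acc <- build$result$models$accuracy
    acc <- acc[!build$result$models$failed & !is.na(acc)]
    if (!length(acc)) {
      return(NA_real_)
    }
    if (statistic == "min_accuracy") min(acc) else mean(acc)
  }
  model_acc <- function(build) {
    out <- setNames(build$result$models$accuracy, build$result$models$model)
    out[build$result$models$failed] <- NA_real_
    out
  }
  observed <- observed %||% iterate_build(data, config, seed = seed,
                                          regions = regions)
  obs_stat <- stat_fun(observed)
  obs_model <- model_acc(observed)
  perm_seeds <- with_seed(seed, sample.int(2^31 - 2, n_reps))
  null_stats <- numeric(n_reps)
  null_model <- matrix(NA_real_, n_reps, length(obs_model),
                       dimnames = list(NULL, names(obs_model)))
  shuffled <- data
  for (r in seq_len(n_reps)) {
    shuffled$group <- with_seed(perm_seeds[r], sample(data$group))
    build <- suppressWarnings(
      iterate_build(shuffled, config, seed = perm_seeds[r],
                    regions = regions)
    )
    null_stats[r] <- stat_fun(build)
    null_model[r, ] <- model_acc(build)
  }
  p_value <- (1 + sum(null_stats >= obs_stat, na.rm = TRUE)) / (n_reps + 1)
  per_model <- tibble::tibble(
    model = names(obs_model),
    accuracy = unname(obs_model),
    p_value = vapply(seq_along(obs_model), function(i) {
      if (is.na(obs_model[i])) {
        return(NA_real_)
      }
      (1 + sum(null_model[, i] >= obs_model[i], na.rm = TRUE)) / (n_reps + 1)
    }, numeric(1))
  )
  structure(
    list(statistic = statistic, observed = obs_stat,
         null_statistics = null_stats, p_value = p_value,
         per_model = per_model,
         bonferroni_alpha = 0.05 / sum(!is.na(obs_model)),
         n_reps = as.integer(n_reps), observed_build = observed),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %s = %.3f, %d reps, p = %.4g (Bonferroni alpha %.4g)\n",
    x$statistic, x$observed, x$n_reps, x$p_value, x$bonferroni_alpha
  ))
  invisible(x)
}
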