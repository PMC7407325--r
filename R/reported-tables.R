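# Accessors for the reference study's printed result tables, shipped as
# plain TSV under inst/extdata. These are inputs for worked-example
# arithmetic (accuracy averaging, region bookkeeping), not package outputs.

#' Reported per-model validation accuracies (both scan days)
#'
#' The nine per-model test-set accuracies (percent) reported by the
#' reference study for the pre-exercise (day 1) and post-exercise (day 2)
#' models.
#'
#' @return Tibble: `model`, `day1_accuracy`, `day2_accuracy`.
#' @export
reported_model_accuracies <- function() {
  path <- system.file("extdata", "reported_model_accuracy.tsv",
                      package = "fmribucket", mustWork = TRUE)
  tibble::as_tibble(read.delim(path, check.names = FALSE))
}

#' Reported final model regions and their importance metrics
#'
#' The atlas regions retained by the reference study's final day-1 and
#' day-2 models, with the reported random-forest importance and linear-SVM
#' / logistic coefficients. `selected` records whether a region appears in
#' both days' models or only one. (The source table prints uniformly
#' negative "Random Forest Importance" values, a convention impurity
#' importances cannot produce; the values are shipped verbatim and only
#' used for bookkeeping.)
#'
#' @return Tibble: `feature`, `selected` (`both`/`day1`/`day2`), and per-day
#'   importance/coefficient columns (`NA` where a region is not in that
#'   day's model).
#' @export
reported_selected_regions <- function() {
  path <- system.file("extdata", "reported_selected_regions.tsv",
                      package = "fmribucket", mustWork = TRUE)
  tibble::as_tibble(read.delim(path, check.names = FALSE))
}

#' Region bookkeeping of the reported final models
#'
#' Counts of regions in each day's final model and of regions shared by
#' both, computed from [reported_selected_regions()].
#'
#' @return Tibble with `day1_regions`, `day2_regions`, `shared_regions`.
#' @export
reported_region_counts <- function() {
  tab <- reported_selected_regions()
  tibble::tibble(
    day1_regions = sum(tab$selected %in% c("both", "day1")),
    day2_regions = sum(tab$selected %in% c("both", "day2")),
    shared_regions = sum(tab$selected == "both")
  )
}
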