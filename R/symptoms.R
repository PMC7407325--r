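#' Symptom-severity vs. region correlation matrix for one group
#'
#' Pearson correlation of each symptom-severity score against the
#' suprathreshold voxel count of each selected region, over the subjects of
#' one group. Constant columns (either side) yield missing entries, flagged
#' in the `"constant_cells"` attribute.
#'
#' @param data Cohort table with `group`, symptom columns and region
#'   columns.
#' @param selected Region columns to correlate (e.g. a final model's
#'   feature set).
#' @param group Group label to subset on (needs >= 3 members).
#' @param symptoms Symptom score columns (default the nine `sev_*` items).
#' @return Numeric matrix, symptoms x regions, class `symptom_cor`.
#' @export
symptom_region_correlation <- function(data, selected, group,
                                       symptoms = intersect(SYMPTOM_COLS,
                                                            names(data))) {
  stopifnot("group" %in% names(data), length(symptoms) >= 1)
  if (!group %in% data$group) {
    stop(sprintf("group '%s' absent from the table", group), call. = FALSE)
  }
  if (!all(selected %in% names(data))) {
    stop("`selected` must be columns of `data`", call. = FALSE)
  }
  sub <- as.data.frame(data)[data$group == group, , drop = FALSE]
  if (nrow(sub) < 3) {
    stop("group needs at least 3 members", call. = FALSE)
  }
  S <- as.matrix(sub[, symptoms, drop = FALSE])
  R <- as.matrix(sub[, selected, drop = FALSE])
  M <- suppressWarnings(cor(S, R))
  const <- which(is.na(M), arr.ind = TRUE)
  structure(M, group = group, constant_cells = const,
            class = c("symptom_cor", "matrix", "array"))
}

#' Difference of two symptom-correlation matrices
#'
#' Element-wise `mat_b - mat_a` (conventionally GWI minus CFS); missing
#' entries propagate. Row and column labels must match.
#'
#' @param mat_b,mat_a Matrices with identical dimnames (e.g. from
#'   [symptom_region_correlation()]).
#' @return Matrix of differences, class `symptom_cor_diff`.
#' @export
correlation_difference <- function(mat_b, mat_a) {
  if (!identical(dim(mat_b), dim(mat_a)) ||
      !identical(dimnames(mat_b), dimnames(mat_a))) {
    stop("matrices must share shape and labels", call. = FALSE)
  }
  structure(unclass(mat_b) - unclass(mat_a),
            groups = c(attr(mat_b, "group"), attr(mat_a, "group")),
            class = c("symptom_cor_diff", "matrix", "array"))
}
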