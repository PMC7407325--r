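#' Pearson correlation matrix of a feature table
#'
#' Sample Pearson correlations between every pair of features. Constant
#' columns yield missing rows/columns (reported via a warning attribute
#' rather than an error): a constant feature carries no collinearity risk
#' and is left for importance pruning downstream.
#'
#' @param X Subjects x features numeric matrix, or a data frame with region
#'   columns.
#' @param regions Feature columns to use when `X` is a data frame.
#' @return Symmetric correlation matrix with unit diagonal; attribute
#'   `constant_cols` names any zero-variance features.
#' @export
#' @examples
#' pearson_matrix(cbind(a = c(1, 2, 3), b = c(1, 2, 4)))["a", "b"]
pearson_matrix <- function(X, regions = NULL) {
  if (is.data.frame(X)) {
    X <- region_matrix(X, regions %||% region_cols(X))
  }
  X <- as.matrix(X)
  if (nrow(X) < 3) {
    stop("need at least 3 rows to estimate correlations", call. = FALSE)
  }
  sds <- apply(X, 2, sd)
  constant <- colnames(X)[sds == 0] %||% which(sds == 0)
  R <- suppressWarnings(cor(X))
  diag(R) <- 1
  attr(R, "constant_cols") <- constant
  R
}

new_correlation_report <- function(matrices, threshold, flagged, merges) {
  structure(
    list(matrices = matrices, threshold = threshold,
         flagged_pairs = flagged, merges = merges),
    class = "correlation_report"
  )
}

#' Flag collinear feature pairs across train, test and combined sets
#'
#' Computes the Pearson matrix three times (training set, testing set, and
#' both combined, mirroring the study's screening protocol) and flags every
#' pair whose absolute correlation reaches the threshold in *any* of the
#' three. Features passed to model building must all sit below R < 0.9, so
#' ties at exactly the threshold are flagged.
#'
#' @param train,test Feature tables (data frames with region columns) or
#'   numeric matrices with identical feature sets.
#' @param combined Optional combined table; defaults to stacking train and
#'   test.
#' @param threshold Absolute-correlation flag threshold (default 0.9).
#' @param regions Feature columns when inputs are data frames.
#' @return A `correlation_report`: the three matrices, the threshold, a
#'   tibble of flagged pairs (`feature_i`, `feature_j`, `dataset`, `abs_r`)
#'   and an (initially empty) merge audit trail.
#' @export
flag_collinear_pairs <- function(train, test, combined = NULL,
                                 threshold = 0.9, regions = NULL) {
  to_mat <- function(d) {
    if (is.data.frame(d)) region_matrix(d, regions %||% region_cols(d)) else as.matrix(d)
  }
  Xtr <- to_mat(train)
  Xte <- to_mat(test)
  if (!identical(colnames(Xtr), colnames(Xte))) {
    stop("train and test must share an identical feature set", call. = FALSE)
  }
  Xall <- if (is.null(combined)) rbind(Xtr, Xte) else to_mat(combined)
  mats <- list(train = pearson_matrix(Xtr), test = pearson_matrix(Xte),
               combined = pearson_matrix(Xall))
  flagged <- purrr::map_dfr(names(mats), function(nm) {
    R <- mats[[nm]]
    idx <- which(upper.tri(R) & !is.na(R) & abs(R) >= threshold,
                 arr.ind = TRUE)
    if (nrow(idx) == 0) {
      return(tibble::tibble(feature_i = character(), feature_j = character(),
                            dataset = character(), abs_r = numeric()))
    }
    tibble::tibble(
      feature_i = colnames(R)[idx[, 1]],
      feature_j = colnames(R)[idx[, 2]],
      dataset = nm,
      abs_r = abs(R[idx])
    )
  })
  new_correlation_report(mats, threshold, flagged,
                         tibble::tibble(new_name = character(),
                                        members = list()))
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf(
    "<correlation_report> %d features, threshold |R| >= %g, %d flagged pair(s), %d merge(s)\n",
    ncol(x$matrices$combined), x$threshold,
    nrow(dplyr::distinct(x$flagged_pairs, .data$feature_i, .data$feature_j)),
    nrow(x$merges)
  ))
  invisible(x)
}

# Connected components of the flagged-pair graph (union-find).
pair_components <- function(features, pairs) {
  parent <- setNames(seq_along(features), features)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ri <- find(match(pairs$feature_i[k], features))
    rj <- find(match(pairs$feature_j[k], features))
    if (ri != rj) parent[rj] <- ri
  }
  roots <- vapply(seq_along(features), find, numeric(1))
  split(features, roots)
}

#' Merge collinear features by summing their counts
#'
#' Replaces each connected component of the flagged-pair graph by a single
#' combined feature whose entries are the summed member counts (counts are
#' additive), then re-screens and repeats until no pair is flagged. The
#' merge audit trail records every combined feature and its members. With no
#' flagged pairs the input is returned unchanged.
#'
#' @param X Feature matrix or data frame whose features match the report.
#' @param report A `correlation_report` built on these features.
#' @param regions Feature columns when `X` is a data frame.
#' @return List with `X` (reduced matrix) and `report` (updated, with zero
#'   remaining flags).
#' @export
merge_collinear <- function(X, report, regions = NULL) {
  stopifnot(inherits(report, "correlation_report"))
  if (is.data.frame(X)) {
    X <- region_matrix(X, regions %||% region_cols(X))
  }
  merges <- report$merges
  threshold <- report$threshold
  flagged <- dplyr::distinct(report$flagged_pairs, .data$feature_i,
                             .data$feature_j)
  repeat {
    if (nrow(flagged) == 0) break
    comps <- pair_components(colnames(X), flagged)
    keep <- comps[lengths(comps) == 1]
    merged <- comps[lengths(comps) > 1]
    new_cols <- lapply(merged, function(members) {
      rowSums(X[, members, drop = FALSE])
    })
    new_names <- vapply(merged, paste, character(1), collapse = "+")
    merges <- dplyr::bind_rows(
      merges,
      tibble::tibble(new_name = new_names, members = unname(merged))
    )
    X <- cbind(
      X[, unlist(keep), drop = FALSE],
      matrix(unlist(new_cols), nrow = nrow(X),
             dimnames = list(NULL, new_names))
    )
    R <- pearson_matrix(X)
    idx <- which(upper.tri(R) & !is.na(R) & abs(R) >= threshold,
                 arr.ind = TRUE)
    flagged <- tibble::tibble(feature_i = colnames(R)[idx[, 1]],
                              feature_j = colnames(R)[idx[, 2]])
  }
  report$merges <- merges
  report$flagged_pairs <- report$flagged_pairs[0, ]
  list(X = X, report = report)
}

#' Screen a split cohort for multicollinearity
#'
#' Convenience wrapper running [flag_collinear_pairs()] on the training,
#' testing and combined tables and applying the same [merge_collinear()]
#' merges consistently to both splits, iterating until no pair is flagged in
#' any of the three matrices.
#'
#' @param train,test Feature tables sharing a feature set.
#' @param threshold Absolute-correlation threshold (default 0.9).
#' @param regions Feature columns when inputs are data frames.
#' @return List with `train`, `test` (reduced matrices) and the final
#'   `correlation_report`.
#' @export
screen_features <- function(train, test, threshold = 0.9, regions = NULL) {
  to_mat <- function(d) {
    if (is.data.frame(d)) region_matrix(d, regions %||% region_cols(d)) else as.matrix(d)
  }
  Xtr <- to_mat(train)
  Xte <- to_mat(test)
  merges <- tibble::tibble(new_name = character(), members = list())
  repeat {
    report <- flag_collinear_pairs(Xtr, Xte, threshold = threshold)
    flagged <- dplyr::distinct(report$flagged_pairs, .data$feature_i,
                               .data$feature_j)
    if (nrow(flagged) == 0) {
      report$merges <- merges
      return(list(train = Xtr, test = Xte, report = report))
    }
    comps <- pair_components(colnames(Xtr), flagged)
    keep <- unlist(comps[lengths(comps) == 1])
    merged <- comps[lengths(comps) > 1]
    new_names <- vapply(merged, paste, character(1), collapse = "+")
    merges <- dplyr::bind_rows(
      merges, tibble::tibble(new_name = new_names, members = unname(merged))
    )
    combine <- function(X) {
      cbind(
        X[, keep, drop = FALSE],
        matrix(vapply(merged, function(m) rowSums(X[, m, drop = FALSE]),
                      numeric(nrow(X))),
               nrow = nrow(X), dimnames = list(NULL, new_names))
      )
    }
    Xtr <- combine(Xtr)
    Xte <- combine(Xte)
  }
}

#' Quartile-bin features on training-set boundaries
#'
#' Maps each feature to ordinal codes 1-4 by its training-set quartiles
#' (Q1: below the 25th percentile, Q2: 25-50, Q3: 50-75, Q4: above the 75th).
#' The boundaries are persisted in the result so a held-out set can be coded
#' on the training boundaries. An optional transform in the model build, off
#' by default.
#'
#' @param X Numeric matrix or feature table (at least 4 rows when boundaries
#'   are being estimated).
#' @param boundaries Optional 3 x features matrix of persisted quartile
#'   boundaries (from a previous call); when `NULL` they are estimated from
#'   `X`.
#' @param regions Feature columns when `X` is a data frame.
#' @return Integer-coded matrix with attribute `boundaries`. Degenerate
#'   (all-equal) columns code as 1 with a warning.
#' @export
#' @examples
#' quartile_bin(matrix(c(1, 2, 3, 4), ncol = 1))
quartile_bin <- function(X, boundaries = NULL, regions = NULL) {
  if (is.data.frame(X)) {
    X <- region_matrix(X, regions %||% region_cols(X))
  }
  X <- as.matrix(X)
  if (is.null(boundaries)) {
    if (nrow(X) < 4) {
      stop("need at least 4 rows to estimate quartile boundaries",
           call. = FALSE)
    }
    boundaries <- apply(X, 2, quantile, probs = c(0.25, 0.5, 0.75),
                        names = FALSE)
    boundaries <- matrix(boundaries, nrow = 3,
                         dimnames = list(c("q25", "q50", "q75"), colnames(X)))
  }
  degenerate <- boundaries["q25", ] == boundaries["q75", ]
  if (any(degenerate)) {
    warning(sprintf("%d feature(s) with degenerate quartile boundaries",
                    sum(degenerate)), call. = FALSE)
  }
  codes <- 1L +
    (X > matrix(boundaries["q25", ], nrow(X), ncol(X), byrow = TRUE)) +
    (X > matrix(boundaries["q50", ], nrow(X), ncol(X), byrow = TRUE)) +
    (X > matrix(boundaries["q75", ], nrow(X), ncol(X), byrow = TRUE))
  storage.mode(codes) <- "integer"
  dimnames(codes) <- dimnames(X)
  attr(codes, "boundaries") <- boundaries
  codes
}
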