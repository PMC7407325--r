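# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so package functions never clobber user seeds.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Columns of `data` holding region voxel counts. Uses the "region_cols"
# attribute when present, otherwise any column matching the default
# region-name prefix.
#' Region feature columns of a cohort table
#'
#' Returns the names of the columns of `data` that hold per-region
#' suprathreshold voxel counts: the `"region_cols"` attribute if set by the
#' function that built the table, otherwise all columns whose name starts
#' with `"region_"`.
#'
#' @param data A cohort/feature table (data frame).
#' @return Character vector of column names.
#' @export
region_cols <- function(data) {
  rc <- attr(data, "region_cols")
  if (!is.null(rc)) {
    return(intersect(rc, names(data)))
  }
  grep("^region_", names(data), value = TRUE)
}

set_region_cols <- function(data, cols) {
  attr(data, "region_cols") <- cols
  data
}

# Numeric matrix of the region columns, rows in table order.
region_matrix <- function(data, regions = region_cols(data)) {
  m <- as.matrix(as.data.frame(data)[, regions, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- NULL
  m
}

# Stratified fold assignment: within each class, folds are dealt out in a
# random order so every fold sees both classes whenever possible.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

is_count_scalar <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x) && x >= 0
}
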