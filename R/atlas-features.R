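#' Per-subject t-statistic volume
#'
#' Light container for one subject's 3-D t-statistic map (e.g. a
#' 2-back > 0-back working-memory contrast) with its voxel-to-world affine.
#'
#' @param t_values 3-D numeric array of t-values (NAs allowed).
#' @param affine 4 x 4 voxel-to-world transform (0-based voxel indices).
#' @param subject_id Subject identifier.
#' @param day Scan day, 1 or 2.
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(t_values, affine = diag(4), subject_id = NA_character_,
                     day = 1L) {
  stopifnot(is.array(t_values), length(dim(t_values)) == 3,
            all(dim(affine) == c(4, 4)), day %in% c(1L, 2L))
  if (any(dim(t_values) == 0)) {
    stop("degenerate map: a dimension has extent 0", call. = FALSE)
  }
  structure(
    list(t_values = t_values, affine = affine,
         subject_id = as.character(subject_id), day = as.integer(day)),
    class = "stat_map"
  )
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> subject %s day %d, %s grid\n", x$subject_id, x$day,
              paste(dim(x$t_values), collapse = "x")))
  invisible(x)
}

#' Read a NIfTI t-map into a `stat_map`
#'
#' @param path Path to a NIfTI-1 file.
#' @param subject_id,day Metadata attached to the map.
#' @return A [stat_map()].
#' @export
read_stat_map <- function(path, subject_id = NA_character_, day = 1L) {
  img <- RNifti::readNifti(path)
  stat_map(array(as.numeric(img), dim = dim(img)),
           affine = unclass(RNifti::xform(img)),
           subject_id = subject_id, day = day)
}

#' Write a `stat_map` or atlas to NIfTI-1
#'
#' @param x A `stat_map` or `atlas_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path) {
  arr <- if (inherits(x, "stat_map")) x$t_values else x$labels
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(x$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Binary suprathreshold mask of a t-map
#'
#' Marks the voxels whose t-value strictly exceeds the threshold ("exceeding"
#' is read literally, so a voxel at exactly the threshold is excluded).
#' Missing t-values are treated as subthreshold; their number is reported in
#' a warning and in the `"n_missing"` attribute.
#'
#' @param map A [stat_map()] or a 3-D numeric array.
#' @param t_thresh Finite threshold; default 3.17, the study's p < 0.001
#'   (uncorrected) cut-off.
#' @return Logical array of the map's shape with attribute `n_missing`.
#' @export
#' @examples
#' m <- array(c(3.18, 3.17, 3.16, 0, 0, 0, 0, 0), dim = c(2, 2, 2))
#' sum(threshold_map(m, 3.17))  # only the 3.18 voxel survives
threshold_map <- function(map, t_thresh = 3.17) {
  t_arr <- if (inherits(map, "stat_map")) map$t_values else map
  stopifnot(is.numeric(t_thresh), length(t_thresh) == 1, is.finite(t_thresh))
  if (!is.array(t_arr) || length(dim(t_arr)) != 3) {
    stop("`map` must be a stat_map or 3-D array", call. = FALSE)
  }
  if (any(dim(t_arr) == 0)) {
    stop("degenerate map: a dimension has extent 0", call. = FALSE)
  }
  n_missing <- sum(is.na(t_arr))
  if (n_missing > 0) {
    warning(sprintf("%d missing t-values treated as subthreshold", n_missing),
            call. = FALSE)
  }
  mask <- !is.na(t_arr) & t_arr > t_thresh
  attr(mask, "n_missing") <- n_missing
  mask
}

# Nearest-neighbour resampling of integer atlas labels onto a target grid:
# each target voxel centre is mapped to world space and looked up in the
# atlas grid (labels are categorical, so no interpolation).
resample_atlas_labels <- function(atlas, target_dim, target_affine) {
  ijk <- as.matrix(expand.grid(
    i = seq_len(target_dim[1]) - 1L,
    j = seq_len(target_dim[2]) - 1L,
    k = seq_len(target_dim[3]) - 1L
  ))
  world <- cbind(ijk, 1) %*% t(target_affine)
  src <- world %*% t(solve(atlas$affine))
  src_idx <- round(src[, 1:3]) + 1L
  ok <- src_idx[, 1] >= 1 & src_idx[, 1] <= dim(atlas$labels)[1] &
    src_idx[, 2] >= 1 & src_idx[, 2] <= dim(atlas$labels)[2] &
    src_idx[, 3] >= 1 & src_idx[, 3] <= dim(atlas$labels)[3]
  if (!any(ok)) {
    stop("atlas and map grids do not overlap in world space", call. = FALSE)
  }
  lab <- integer(nrow(ijk))
  lab[ok] <- atlas$labels[src_idx[ok, , drop = FALSE]]
  array(lab, dim = target_dim)
}

#' Count suprathreshold voxels per atlas region
#'
#' Groups the `TRUE` voxels of a suprathreshold mask by atlas label and
#' returns one count per region (background label 0 discarded). When the
#' mask grid differs from the atlas grid the atlas labels are resampled to
#' the mask grid by nearest-neighbour lookup in world space, using the two
#' affines.
#'
#' @param mask Logical 3-D array (e.g. from [threshold_map()]).
#' @param atlas An `atlas_volume`.
#' @param mask_affine Voxel-to-world affine of the mask grid; required only
#'   when the grids differ.
#' @return Named integer vector of length `nrow(atlas$region_table)`.
#' @export
count_voxels_by_region <- function(mask, atlas, mask_affine = NULL) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3,
            inherits(atlas, "atlas_volume"))
  labels <- atlas$labels
  if (!all(dim(mask) == dim(labels))) {
    if (is.null(mask_affine)) {
      stop("mask and atlas grids differ and no `mask_affine` was supplied",
           call. = FALSE)
    }
    labels <- resample_atlas_labels(atlas, dim(mask), mask_affine)
  }
  R <- nrow(atlas$region_table)
  hit <- labels[mask]
  counts <- tabulate(hit[hit > 0], nbins = R)
  setNames(as.integer(counts), atlas$region_table$name)
}

#' Build the subjects x regions voxel-count feature table
#'
#' Applies [threshold_map()] and [count_voxels_by_region()] to each
#' subject's t-map and assembles the result as one row per map, with
#' columns in atlas region order, joined to the supplied subject metadata.
#' Subjects with zero suprathreshold voxels are retained as all-zero rows
#' (and reported via a message).
#'
#' @param maps List of [stat_map()] objects, all from the same scan day.
#' @param atlas An `atlas_volume`.
#' @param t_thresh Threshold passed to [threshold_map()] (default 3.17).
#' @param metadata Data frame with a `subject_id` column (and typically
#'   `group`, `age`, `sex`, `bmi`, symptom scores) covering every map.
#' @return A tibble (metadata columns, then one count column per region)
#'   with attributes `region_cols` and `threshold`.
#' @export
build_feature_table <- function(maps, atlas, t_thresh = 3.17, metadata) {
  if (length(maps) == 0) {
    stop("`maps` is empty: nothing to featurize", call. = FALSE)
  }
  stopifnot(all(vapply(maps, inherits, logical(1), "stat_map")),
            inherits(atlas, "atlas_volume"), is.data.frame(metadata),
            "subject_id" %in% names(metadata))
  ids <- vapply(maps, function(m) m$subject_id, character(1))
  days <- vapply(maps, function(m) m$day, integer(1))
  if (length(unique(days)) > 1) {
    stop("all maps must come from the same scan day", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate subject_id among maps for this day", call. = FALSE)
  }
  if (!all(ids %in% metadata$subject_id)) {
    stop("metadata is missing some map subject_ids", call. = FALSE)
  }
  counts <- t(vapply(maps, function(m) {
    mask <- threshold_map(m, t_thresh)
    count_voxels_by_region(mask, atlas, mask_affine = m$affine)
  }, integer(nrow(atlas$region_table))))
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    message(sprintf("%d subject(s) with zero suprathreshold voxels retained",
                    sum(empty)))
  }
  md <- dplyr::left_join(tibble::tibble(subject_id = ids),
                         tibble::as_tibble(metadata), by = "subject_id")
  out <- dplyr::bind_cols(md, tibble::as_tibble(counts))
  out$day <- days[1]
  out <- set_region_cols(out, atlas$region_table$name)
  attr(out, "threshold") <- t_thresh
  out
}
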