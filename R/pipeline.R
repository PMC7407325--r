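#' Default pipeline configuration
#'
#' The resolved configuration structure consumed by [run_pipeline()]:
#' a synthetic-cohort section (or file inputs), the feature-extraction
#' threshold, the collinearity screen threshold, the bucket build settings
#' and the optional shuffle test. Any YAML file with the same nesting can
#' be passed to [run_pipeline()] directly.
#'
#' @param ... Named overrides merged (shallowly per section) into the
#'   defaults.
#' @return Nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    mode = "synthetic",
    seed = 1L,
    day = 1L,
    threshold = 3.17,
    synthetic = list(
      n_group_a = 38L, n_group_b = 80L, n_regions = 117L,
      grid_shape = c(24L, 24L, 24L), baseline_count_mean = 15,
      dispersion = 8, effect_regions = 1:5, effect_size = 1.5,
      mode = "table"
    ),
    files = list(maps_dir = NULL, atlas = NULL, metadata = NULL),
    screen = list(threshold = 0.9),
    bucket = list(),
    shuffle = list(enabled = FALSE, n_reps = 200L)
  )
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

validate_pipeline_config <- function(cfg) {
  if (!cfg$mode %in% c("synthetic", "files")) {
    stop("config mode must be 'synthetic' or 'files'", call. = FALSE)
  }
  if (!cfg$day %in% c(1, 2)) {
    stop("config day must be 1 or 2", call. = FALSE)
  }
  stopifnot(is.numeric(cfg$threshold), is.numeric(cfg$seed))
  if (cfg$mode == "files" &&
      (is.null(cfg$files$atlas) || is.null(cfg$files$metadata))) {
    stop("files mode needs `files$atlas` and `files$metadata`",
         call. = FALSE)
  }
  invisible(cfg)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the end-to-end discrimination pipeline
#'
#' Executes the full build in the stage order of the study design: obtain
#' per-subject data (synthetic generation or NIfTI t-maps + atlas +
#' metadata from disk), extract the suprathreshold voxel-count feature
#' table, screen it for multicollinearity, run the iterative bucket build,
#' derive the consensus agreement-threshold curve, compute the per-group
#' symptom-severity correlation matrices and their difference over the
#' final model regions, and (optionally) the label-shuffle permutation
#' test. All artifacts are written as plain tables (TSV/CSV/JSON) plus the
#' resolved configuration and a run log with the seed and config hash.
#'
#' @param config A `pipeline_config`, a plain nested list, or a path to a
#'   YAML file with the same structure.
#' @param out_dir Output directory (created; must not pre-exist unless
#'   `overwrite = TRUE`). `NULL` skips writing.
#' @param seed Optional seed overriding the config's.
#' @param overwrite Allow writing into an existing directory.
#' @return Invisibly, a list with `feature_table`, `screen`, `build`,
#'   `curve`, `symptom` (per-group matrices and difference), `shuffle`
#'   (or `NULL`), `config`, and `out_dir`; class `pipeline_bundle`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         seed = NULL, overwrite = FALSE) {
  if (is.character(config)) {
    config <- read_pipeline_config(config)
  } else if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
  }
  validate_pipeline_config(config)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  # -- stage 1: inputs --------------------------------------------------------
  if (config$mode == "synthetic") {
    syn <- config$synthetic
    spec <- cohort_spec(
      n_group_a = syn$n_group_a, n_group_b = syn$n_group_b,
      n_regions = syn$n_regions, grid_shape = syn$grid_shape,
      baseline_count_mean = syn$baseline_count_mean,
      dispersion = syn$dispersion,
      effect_regions = syn$effect_regions, effect_size = syn$effect_size,
      # day 2 draws an independent cohort realization from an offset seed
      seed = config$seed + (config$day - 1L) * 1000L
    )
    cohort <- clock("simulate", generate_cohort(spec, mode = syn$mode))
    atlas <- cohort$atlas
    feature_table <- clock("featurize", {
      if (identical(syn$mode, "maps")) {
        md <- cohort$table[, setdiff(names(cohort$table),
                                     region_cols(cohort$table))]
        build_feature_table(unname(cohort$maps), atlas,
                            t_thresh = config$threshold, metadata = md)
      } else {
        cohort$table
      }
    })
  } else {
    atlas <- clock("read_atlas", read_atlas_nifti(config$files$atlas))
    metadata <- tibble::as_tibble(read.delim(config$files$metadata))
    paths <- sort(list.files(config$files$maps_dir, "\\.nii(\\.gz)?$",
                             full.names = TRUE))
    maps <- clock("read_maps", lapply(paths, function(p) {
      read_stat_map(p, subject_id = sub("\\.nii(\\.gz)?$", "", basename(p)),
                    day = config$day)
    }))
    feature_table <- clock("featurize", build_feature_table(
      maps, atlas, t_thresh = config$threshold, metadata = metadata
    ))
  }
  feature_table$day <- as.integer(config$day)

  # -- stage 2: collinearity screen ------------------------------------------
  bucket_cfg <- do.call(bucket_config, config$bucket)
  split <- split_cohort(feature_table, ratio = bucket_cfg$split_ratio,
                        seed = config$seed)
  screen <- clock("screen", screen_features(
    feature_table[split$train, ], feature_table[split$test, ],
    threshold = config$screen$threshold
  ))
  screened_table <- feature_table
  merged_names <- colnames(screen$train)
  if (!identical(sort(merged_names), sort(region_cols(feature_table)))) {
    # apply the same merges to the full table
    keep_meta <- setdiff(names(feature_table), region_cols(feature_table))
    full_x <- rbind(screen$train, screen$test)
    ord <- order(c(split$train, split$test))
    screened_table <- dplyr::bind_cols(
      feature_table[, keep_meta],
      tibble::as_tibble(full_x[ord, , drop = FALSE])
    )
    screened_table <- set_region_cols(screened_table, merged_names)
  }

  # -- stage 3-4: selection + bucket build -----------------------------------
  build <- clock("build", iterate_build(screened_table, bucket_cfg,
                                        seed = config$seed))

  # -- stage 5: consensus -----------------------------------------------------
  curve <- clock("consensus", consensus_curve(build))

  # -- stage 6: symptom correlations -----------------------------------------
  symptom <- NULL
  sym_cols <- intersect(SYMPTOM_COLS, names(screened_table))
  if (length(sym_cols) && all(c("CFS", "GWI") %in% screened_table$group)) {
    symptom <- clock("symptoms", {
      cfs <- symptom_region_correlation(screened_table,
                                        build$final_features, "CFS")
      gwi <- symptom_region_correlation(screened_table,
                                        build$final_features, "GWI")
      list(cfs = cfs, gwi = gwi, diff = correlation_difference(gwi, cfs))
    })
  }

  # -- stage 7: shuffle test (optional) --------------------------------------
  shuffle <- NULL
  if (isTRUE(config$shuffle$enabled)) {
    shuffle <- clock("shuffle", shuffle_test(
      screened_table, bucket_cfg, n_reps = config$shuffle$n_reps,
      seed = config$seed + 7L, observed = build
    ))
  }

  bundle <- structure(
    list(feature_table = feature_table, screen = screen, build = build,
         curve = curve, symptom = symptom, shuffle = shuffle,
         config = config, out_dir = out_dir),
    class = "pipeline_bundle"
  )
  if (!is.null(out_dir)) {
    write_pipeline_bundle(bundle, out_dir, overwrite = overwrite,
                          timings = timings)
  }
  invisible(bundle)
}

#' Read an integer-labelled atlas volume from NIfTI
#'
#' @param path NIfTI file of integer region labels (0 = background).
#' @param region_names Optional names, one per label.
#' @return An `atlas_volume`.
#' @export
read_atlas_nifti <- function(path, region_names = NULL) {
  img <- RNifti::readNifti(path)
  labels <- array(as.integer(round(as.numeric(img))), dim = dim(img))
  affine <- unclass(RNifti::xform(img))
  ids <- sort(unique(labels[labels > 0]))
  com <- vapply(ids, function(r) {
    idx <- which(labels == r, arr.ind = TRUE) - 1
    colMeans(cbind(idx, 1) %*% t(affine))[1:3]
  }, numeric(3))
  structure(
    list(labels = labels,
         region_table = tibble::tibble(
           region_id = ids,
           name = region_names %||% region_name(ids),
           com_x = com[1, ], com_y = com[2, ], com_z = com[3, ],
           n_voxels = as.integer(tabulate(labels[labels > 0],
                                          nbins = max(ids))[ids])
         ),
         affine = affine),
    class = "atlas_volume"
  )
}

write_pipeline_bundle <- function(bundle, out_dir, overwrite = FALSE,
                                  timings = list()) {
  if (dir.exists(out_dir) && !overwrite &&
      length(list.files(out_dir)) > 0) {
    stop(sprintf("output directory '%s' already exists and is non-empty",
                 out_dir), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)

  write_tsv(bundle$feature_table, p("feature_table.tsv"))
  jsonlite::write_json(
    list(threshold = bundle$screen$report$threshold,
         flagged_pairs = bundle$screen$report$flagged_pairs,
         merges = purrr::map2(
           bundle$screen$report$merges$new_name,
           bundle$screen$report$merges$members,
           function(nm, mem) list(new_name = nm, members = mem)
         )),
    p("screen_report.json"), auto_unbox = TRUE, digits = NA
  )
  write_tsv(tidy(bundle$build), p("final_features.tsv"))
  log_tab <- bundle$build$log
  log_tab$accuracies <- NULL
  write_tsv(log_tab, p("iteration_log.tsv"))
  write_tsv(tidy(bundle$curve), p("consensus_curve.csv"))
  write_tsv(tidy(bundle$build$result), p("model_accuracies.tsv"))
  if (!is.null(bundle$symptom)) {
    for (nm in names(bundle$symptom)) {
      m <- bundle$symptom[[nm]]
      df <- data.frame(symptom = rownames(m), unclass(m),
                       check.names = FALSE)
      write_tsv(df, p(sprintf("symptom_correlation_%s.tsv", nm)))
    }
  }
  if (!is.null(bundle$shuffle)) {
    jsonlite::write_json(
      list(statistic = bundle$shuffle$statistic,
           observed = bundle$shuffle$observed,
           p_value = bundle$shuffle$p_value,
           n_reps = bundle$shuffle$n_reps,
           bonferroni_alpha = bundle$shuffle$bonferroni_alpha,
           per_model = bundle$shuffle$per_model,
           null_statistics = bundle$shuffle$null_statistics),
      p("permutation.json"), auto_unbox = TRUE, digits = NA
    )
  }
  cfg <- bundle$config
  yaml::write_yaml(unclass(cfg), p("config_resolved.yaml"))
  jsonlite::write_json(
    list(seed = cfg$seed,
         config_hash = rlang::hash(unclass(cfg)),
         converged = bundle$build$converged,
         stop_reason = bundle$build$stop_reason,
         stage_seconds = timings),
    p("run_log.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(out_dir)
}

#' @export
print.pipeline_bundle <- function(x, ...) {
  cat(sprintf(
    "<pipeline_bundle> day %d, %d subjects, %d final feature(s), %s\n",
    x$config$day, nrow(x$feature_table),
    length(x$build$final_features),
    if (x$build$converged) "converged" else "not converged"
  ))
  invisible(x)
}
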