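# Shared fixtures, all generated in code.

tiny_atlas <- function(n_regions = 5, grid = c(8, 8, 8), seed = 1) {
  generate_atlas(n_regions, grid, seed = seed)
}

tiny_cohort <- function(n_a = 8, n_b = 12, n_regions = 6, effect = 0,
                        effect_regions = integer(0), seed = 1,
                        mode = "table", grid = c(8, 8, 8)) {
  spec <- cohort_spec(
    n_group_a = n_a, n_group_b = n_b, n_regions = n_regions,
    grid_shape = grid, effect_regions = effect_regions,
    effect_size = effect, seed = seed
  )
  generate_cohort(spec, mode = mode)
}

# light bucket configuration for fast loop tests
light_config <- function(...) {
  bucket_config(forest_trees = 15, boost_rounds = 8, mlp_size = 2,
                mlp_maxit = 30, ...)
}

# two well-separated Gaussian clusters as a cohort-like tibble
separable_table <- function(n_per_class = 100, p = 3, gap = 10, seed = 1) {
  set.seed(seed)
  X <- rbind(
    matrix(rnorm(n_per_class * p), ncol = p),
    matrix(rnorm(n_per_class * p, mean = gap), ncol = p)
  )
  colnames(X) <- sprintf("region_%03d", seq_len(p))
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(2 * n_per_class)),
    group = factor(rep(c("GWI", "CFS"), each = n_per_class),
                   levels = c("GWI", "CFS"))
  ) |>
    dplyr::bind_cols(tibble::as_tibble(X))
}

# null table: labels independent of features
null_table <- function(n = 200, p = 5, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), ncol = p)
  colnames(X) <- sprintf("region_%03d", seq_len(p))
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = factor(rep(c("GWI", "CFS"), length.out = n),
                   levels = c("GWI", "CFS"))
  ) |>
    dplyr::bind_cols(tibble::as_tibble(X))
}
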