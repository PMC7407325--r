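test_that("generated atlas is an exact partition of the in-mask voxels", {
  for (seed in 1:3) {
    atlas <- tiny_atlas(n_regions = 7, grid = c(10, 9, 8), seed = seed)
    labs <- atlas$labels
    # exhaustive voxel scan: every voxel carries exactly one label and the
    # per-region counts sum to the mask size
    expect_true(all(labs %in% 0:7))
    expect_identical(sum(atlas$region_table$n_voxels), sum(labs > 0))
    expect_identical(
      atlas$region_table$n_voxels,
      vapply(1:7, function(r) sum(labs == r), integer(1))
    )
    expect_true(all(atlas$region_table$n_voxels > 0))
    expect_false(anyDuplicated(atlas$region_table$name) > 0)
  }
})

test_that("single-region atlas labels every in-mask voxel 1", {
  atlas <- tiny_atlas(n_regions = 1, grid = c(6, 6, 6))
  expect_setequal(unique(as.vector(atlas$labels)), c(0L, 1L))
  expect_identical(atlas$region_table$n_voxels, sum(atlas$labels > 0))
})

test_that("default atlas carries 117 regions and generation is deterministic", {
  a1 <- generate_atlas(seed = 42)
  a2 <- generate_atlas(seed = 42)
  expect_identical(nrow(a1$region_table), 117L)
  expect_identical(a1$labels, a2$labels)
  a3 <- generate_atlas(seed = 43)
  expect_false(identical(a1$labels, a3$labels))
})

test_that("atlas generation rejects more regions than voxels", {
  expect_error(generate_atlas(n_regions = 10000, grid_shape = c(6, 6, 6)),
               "fewer")
})

test_that("default cohort has 118 subject rows with the study group sizes", {
  spec <- cohort_spec(seed = 7)
  coh <- generate_cohort(spec)
  expect_identical(nrow(coh$table), 118L)
  expect_identical(sum(coh$table$group == "CFS"), 38L)
  expect_identical(sum(coh$table$group == "GWI"), 80L)
  expect_length(region_cols(coh$table), 117L)
  expect_identical(sum(startsWith(names(coh$table), "sev_")), 9L)
})

test_that("cohort generation is deterministic and seed-sensitive", {
  spec <- cohort_spec(n_group_a = 5, n_group_b = 6, n_regions = 4,
                      grid_shape = c(8, 8, 8), seed = 11)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$table, c2$table)
  spec2 <- cohort_spec(n_group_a = 5, n_group_b = 6, n_regions = 4,
                       grid_shape = c(8, 8, 8), seed = 12)
  expect_false(identical(generate_cohort(spec2)$table, c1$table))
})

test_that("null cohort has equal expected counts in every region", {
  spec <- cohort_spec(n_group_a = 300, n_group_b = 300, n_regions = 3,
                      grid_shape = c(8, 8, 8), effect_size = 0, seed = 5)
  coh <- generate_cohort(spec)
  X <- as.matrix(coh$table[, region_cols(coh$table)])
  for (r in 1:3) {
    d <- t.test(X[coh$table$group == "GWI", r],
                X[coh$table$group == "CFS", r])
    expect_gt(d$p.value, 1e-4)
  }
})

test_that("planted effect matches the nominal pooled SMD at n = 500/group", {
  spec <- cohort_spec(n_group_a = 500, n_group_b = 500, n_regions = 4,
                      grid_shape = c(10, 10, 10), effect_regions = c(1, 3),
                      effect_size = 1, seed = 9)
  coh <- generate_cohort(spec)
  X <- as.matrix(coh$table[, region_cols(coh$table)])
  g <- coh$table$group
  smd <- function(r) {
    a <- X[g == "CFS", r]
    b <- X[g == "GWI", r]
    (mean(b) - mean(a)) / sqrt((var(a) + var(b)) / 2)
  }
  se_smd <- sqrt(1 / 500 + 1 / 500 + 1^2 / (2 * 1000))
  for (r in c(1, 3)) {
    expect_lt(abs(smd(r) - 1), 3 * se_smd)
  }
  for (r in c(2, 4)) {
    expect_lt(abs(smd(r)), 3 * se_smd)
  }
})

test_that("maps mode plants counts that extraction recovers exactly", {
  coh <- tiny_cohort(n_a = 4, n_b = 5, n_regions = 5, mode = "maps",
                     seed = 3)
  ft <- build_feature_table(unname(coh$maps), coh$atlas, t_thresh = 3.17,
                            metadata = coh$table["subject_id"])
  extracted <- as.matrix(ft[, region_cols(ft)])
  dimnames(extracted) <- dimnames(coh$latent_counts)
  expect_identical(extracted, coh$latent_counts)
})

test_that("symptom scores sit at the scale midpoint under zero coupling/noise", {
  spec <- cohort_spec(n_group_a = 4, n_group_b = 4, n_regions = 3,
                      grid_shape = c(8, 8, 8),
                      symptom_coupling = matrix(0, 9, 3),
                      symptom_noise_sd = 0, seed = 2)
  coh <- generate_cohort(spec)
  scores <- as.matrix(coh$table[, paste0("sev_", c(
    "fatigue", "memory_concentration", "sore_throat", "lymph_nodes",
    "muscle_pain", "joint_pain", "headaches", "sleep",
    "exertional_exhaustion"
  ))])
  expect_true(all(scores == 2))
})

test_that("unit coupling with zero noise gives perfect rank correlation", {
  W <- matrix(0, 9, 3)
  W[4, 2] <- 1
  spec <- cohort_spec(n_group_a = 10, n_group_b = 10, n_regions = 3,
                      grid_shape = c(8, 8, 8), symptom_coupling = W,
                      symptom_noise_sd = 0, seed = 6)
  coh <- generate_cohort(spec)
  x <- coh$table[[region_cols(coh$table)[2]]]
  y <- coh$table$sev_lymph_nodes
  # rank correlation oracle (clipping can only tie extremes, none here)
  expect_equal(suppressWarnings(cor(x, y, method = "spearman")), 1,
               tolerance = 1e-12)
})

test_that("symptom scores stay on the 0-4 severity scale", {
  coh <- tiny_cohort(n_a = 20, n_b = 20, n_regions = 4,
                     effect_regions = 1:2, effect = 2, seed = 8)
  scores <- as.matrix(coh$table[, grep("^sev_", names(coh$table))])
  expect_true(all(scores >= 0 & scores <= 4))
  expect_identical(ncol(scores), 9L)
})

test_that("spec validation rejects invalid effect regions and sizes", {
  expect_error(cohort_spec(effect_regions = 120), "effect_regions")
  expect_error(cohort_spec(n_group_a = 1), "n_group_a")
  expect_error(cohort_spec(dispersion = 0))
})
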