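test_that("agreement counts are per-subject sums over models", {
  M <- matrix(FALSE, 3, 4)
  expect_identical(unname(agreement_counts(M)), rep(0L, 4L))
  expect_identical(unname(agreement_counts(!M)), rep(3L, 4L))
  set.seed(3)
  for (i in 1:30) {
    P <- matrix(runif(9 * 20) < 0.4, 9, 20)
    oracle <- vapply(1:20, function(s) sum(P[, s]), integer(1))
    expect_identical(unname(agreement_counts(P)), oracle)
  }
})

test_that("failed-model rows (NA) are excluded from agreement", {
  P <- rbind(c(TRUE, FALSE), c(NA, NA), c(TRUE, TRUE))
  expect_identical(unname(agreement_counts(P)), c(2L, 1L))
})

test_that("hand-enumerated 5-subject example reproduces exactly", {
  counts <- c(3, 1, 2, 0, 0)
  labels <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  row <- segment_metrics(counts, labels, k = 2, n_models = 3)
  expect_identical(row$n_selected, 2L)
  expect_identical(row$true_positives, 1L)
  expect_equal(row$precision, 0.5)
  expect_equal(row$sensitivity, 0.5)
  expect_equal(row$fdr, 0.5)
  expect_equal(row$specificity, 2 / 3)
  # k = 1..3 rows against hand enumeration
  r1 <- segment_metrics(counts, labels, 1, 3)
  expect_identical(r1$n_selected, 3L)
  expect_equal(r1$sensitivity, 1)
  r3 <- segment_metrics(counts, labels, 3, 3)
  expect_identical(r3$n_selected, 1L)
  expect_equal(r3$precision, 1)
})

test_that("segment metrics match a brute-force oracle on random inputs", {
  set.seed(5)
  for (i in 1:50) {
    m <- sample(3:9, 1)
    n <- sample(5:25, 1)
    counts <- sample(0:m, n, replace = TRUE)
    labels <- runif(n) < 0.4
    k <- sample(m, 1)
    row <- segment_metrics(counts, labels, k, m)
    sel <- which(counts >= k)
    expect_identical(row$n_selected, length(sel))
    expect_identical(row$true_positives, sum(labels[sel]))
    if (length(sel)) {
      expect_equal(row$precision, sum(labels[sel]) / length(sel))
      expect_equal(row$precision + row$fdr, 1)
    } else {
      expect_true(is.na(row$precision))
    }
    if (any(labels)) {
      expect_equal(row$sensitivity, sum(labels[sel]) / sum(labels))
    }
  }
})

test_that("consensus curves nest and perfect models give precision 1", {
  tab <- separable_table(60, p = 2, gap = 10, seed = 7)
  b <- iterate_build(tab, light_config(covariate_mode = "none",
                                       use_rfe = FALSE), seed = 3)
  cc <- consensus_curve(b)
  expect_true(all(diff(cc$n_selected) <= 0))
  nz <- cc$n_selected > 0
  expect_true(all(cc$precision[nz] == 1))
  expect_true(all(cc$fdr[nz] == 0))
  # nesting: selected(k+1) subset of selected(k) holds by construction of
  # counts >= k, verified through monotone n_selected above plus rates
  expect_true(all(cc$precision[nz] + cc$fdr[nz] == 1))
})

test_that("identical predictions across models give identical rows", {
  pred <- matrix(rep(c(TRUE, FALSE, TRUE, FALSE), each = 1), 4, 4,
                 byrow = TRUE)
  pred <- rbind(pred[1, ], pred[1, ], pred[1, ])
  res <- structure(
    list(models = tibble::tibble(model = c("a", "b", "c"),
                                 label = c("a", "b", "c"),
                                 accuracy = c(0.5, 0.5, 0.5),
                                 failed = rep(FALSE, 3)),
         predictions = pred,
         test_y = factor(c("CFS", "GWI", "CFS", "GWI"),
                         levels = c("GWI", "CFS")),
         positive_class = "CFS", features_used = "f1", iteration = 1L),
    class = "bucket_result"
  )
  cc <- consensus_curve(res)
  nz <- cc$n_selected > 0
  expect_identical(length(unique(cc$n_selected[nz])), 1L)
  expect_identical(length(unique(cc$precision[nz])), 1L)
})

test_that("accuracy summary reproduces the reported day means and SDs", {
  tab <- reported_model_accuracies()
  d1 <- accuracy_summary(tab$day1_accuracy)
  d2 <- accuracy_summary(tab$day2_accuracy)
  expect_identical(round(d1$mean), 75)
  expect_identical(round(d1$sd), 5)
  expect_identical(round(d2$mean), 79)
  expect_identical(round(d2$sd), 2)
})

test_that("the add-one rule gives p = 1/100 when observed beats 99 nulls", {
  # strongly separable cohort: observed min accuracy is 1, no null matches
  tab <- separable_table(n_per_class = 12, p = 2, gap = 12, seed = 9)
  cfg <- light_config(covariate_mode = "none", use_rfe = FALSE,
                      max_iterations = 1, floor_eval = "test")
  st <- suppressWarnings(shuffle_test(tab, cfg, n_reps = 99, seed = 11))
  expect_equal(st$observed, 1)
  expect_lt(max(st$null_statistics), 1)
  expect_equal(st$p_value, 1 / 100)
  expect_length(st$null_statistics, 99L)
  expect_equal(st$bonferroni_alpha, 0.05 / 9)
  expect_true(all(tidy(st)$p_value <= 1))
})

test_that("planted effects raise unanimous precision above single-model", {
  # moderate effect: the unanimous segment should be cleaner than k = 1
  wins <- 0L
  for (s in 1:5) {
    coh <- tiny_cohort(n_a = 19, n_b = 40, n_regions = 8,
                       effect_regions = 1:3, effect = 2, seed = 50 + s)
    b <- suppressWarnings(
      iterate_build(coh$table, light_config(), seed = 50 + s)
    )
    g <- glance(consensus_curve(b))
    if (!is.na(g$precision_kM) && !is.na(g$precision_k1) &&
        g$precision_kM > g$precision_k1) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 4L)
})
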