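test_that("a 118-subject cohort splits 59/59, stratified 19/40 vs 19/40", {
  coh <- tiny_cohort(n_a = 38, n_b = 80, n_regions = 3, seed = 2)
  sp <- split_cohort(coh$table, ratio = 0.5, seed = 1)
  expect_length(sp$train, 59L)
  expect_length(sp$test, 59L)
  g <- coh$table$group
  expect_identical(sum(g[sp$train] == "CFS"), 19L)
  expect_identical(sum(g[sp$train] == "GWI"), 40L)
  expect_identical(sum(g[sp$test] == "CFS"), 19L)
  expect_identical(sum(g[sp$test] == "GWI"), 40L)
})

test_that("splits are disjoint, exhaustive and deterministic", {
  coh <- tiny_cohort(n_a = 7, n_b = 9, n_regions = 3, seed = 4)
  for (seed in 1:5) {
    sp <- split_cohort(coh$table, ratio = 0.6, seed = seed)
    expect_length(intersect(sp$train, sp$test), 0L)
    expect_setequal(c(sp$train, sp$test), seq_len(16))
    expect_identical(sp, split_cohort(coh$table, ratio = 0.6, seed = seed))
  }
  tiny <- tibble::tibble(group = factor(c("GWI", "CFS", "CFS")))
  expect_error(split_cohort(tiny, 0.5, 1), "at least 2")
})

test_that("constant covariates leave features untouched", {
  X <- matrix(rnorm(12), 6, 2)
  covs <- data.frame(age = rep(50, 6), bmi = rep(25, 6))
  out <- residualize_covariates(X[1:4, ], X[5:6, ], covs[1:4, ],
                                covs[5:6, ])
  expect_identical(out$train, X[1:4, ])
  expect_identical(out$test, X[5:6, ])
})

test_that("a feature exactly linear in a covariate residualizes to zero", {
  age <- c(40, 50, 60)
  X <- matrix(2 + 3 * age, ncol = 1)
  out <- residualize_covariates(X, X, data.frame(age = age),
                                data.frame(age = age))
  expect_equal(unname(out$train), matrix(0, 3, 1), tolerance = 1e-10)
  expect_equal(unname(out$test), matrix(0, 3, 1), tolerance = 1e-10)
})

test_that("residualizing an independent covariate preserves residual variance", {
  set.seed(21)
  n <- 200
  x <- rnorm(n)
  cov_real <- rnorm(n)  # genuinely independent of x
  base <- var(residualize_covariates(
    matrix(x), matrix(x), data.frame(c1 = cov_real),
    data.frame(c1 = cov_real)
  )$train[, 1])
  # Monte-Carlo oracle: shuffling the covariate leaves residual variance
  # unchanged within tolerance
  vs <- vapply(1:20, function(i) {
    shuf <- sample(cov_real)
    var(residualize_covariates(
      matrix(x), matrix(x), data.frame(c1 = shuf),
      data.frame(c1 = shuf)
    )$train[, 1])
  }, numeric(1))
  expect_lt(max(abs(vs - base)) / base, 0.1)
})

test_that("rank-deficient covariate designs are rejected", {
  X <- matrix(rnorm(8), 4, 2)
  covs <- data.frame(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  expect_error(residualize_covariates(X, X, covs, covs), "rank-deficient")
})

test_that("RFE retains a perfectly separating feature among noise", {
  set.seed(25)
  n <- 40
  X <- cbind(matrix(rnorm(n * 6), n, 6),
             signal = rep(c(-3, 3), each = n / 2))
  colnames(X)[1:6] <- sprintf("noise%d", 1:6)
  y <- factor(rep(c("GWI", "CFS"), each = n / 2), levels = c("GWI", "CFS"))
  out <- recursive_feature_elimination(X, y, seed = 1)
  expect_true("signal" %in% out$features)
  # refit oracle: the selected subset actually separates
  fit <- fmribucket:::fit_ridge_logistic(X[, out$features, drop = FALSE], y)
  prob <- fmribucket:::predict_ridge_logistic(fit,
                                              X[, out$features,
                                                drop = FALSE])
  expect_gt(mean((prob >= 0.5) == (y == "CFS")), 0.95)
})

test_that("RFE keeps two jointly required features", {
  set.seed(27)
  n <- 60
  x1 <- rnorm(n)
  x2 <- rnorm(n)
  y <- factor(ifelse(x1 + x2 > 0, "CFS", "GWI"), levels = c("GWI", "CFS"))
  X <- cbind(a = x1, b = x2, c = rnorm(n))
  out <- recursive_feature_elimination(X, y, seed = 2)
  expect_true(all(c("a", "b") %in% out$features))
})

test_that("RFE elimination order is a permutation of the features", {
  set.seed(29)
  X <- matrix(rnorm(30 * 5), 30, 5,
              dimnames = list(NULL, letters[1:5]))
  y <- factor(rep(c("GWI", "CFS"), 15), levels = c("GWI", "CFS"))
  out <- recursive_feature_elimination(X, y, seed = 3)
  expect_setequal(out$ranking, letters[1:5])
  expect_identical(anyDuplicated(out$ranking), 0L)
})

test_that("every model reaches accuracy 1 on well-separated clusters", {
  tab <- separable_table(n_per_class = 100, p = 3, gap = 10, seed = 31)
  sp <- split_cohort(tab, 0.5, seed = 1)
  X <- as.matrix(tab[, region_cols(tab)])
  res <- fit_bucket(X[sp$train, ], tab$group[sp$train],
                    X[sp$test, ], tab$group[sp$test],
                    config = light_config(), seed = 1)
  expect_false(any(res$models$failed))
  expect_true(all(res$models$accuracy == 1))
})

test_that("null-data accuracies sit inside the 99% binomial band", {
  tab <- null_table(n = 200, p = 5, seed = 33)
  sp <- split_cohort(tab, 0.5, seed = 2)
  X <- as.matrix(tab[, region_cols(tab)])
  res <- fit_bucket(X[sp$train, ], tab$group[sp$train],
                    X[sp$test, ], tab$group[sp$test],
                    config = light_config(), seed = 2)
  n_test <- length(sp$test)
  maj <- max(table(tab$group[sp$test])) / n_test
  band <- qbinom(c(0.005, 0.995), n_test, maj) / n_test
  ok <- !res$models$failed
  expect_true(all(res$models$accuracy[ok] >= band[1] - 1e-9))
  expect_true(all(res$models$accuracy[ok] <= band[2] + 1e-9))
})

test_that("forest importances are normalized with per-tree standard errors", {
  tab <- separable_table(n_per_class = 30, p = 4, gap = 4, seed = 35)
  X <- as.matrix(tab[, region_cols(tab)])
  fit <- fmribucket:::fit_forest(X, tab$group, ntree = 25, seed = 1)
  imp <- fmribucket:::forest_importance(fit)
  expect_equal(sum(imp$importance), 1, tolerance = 1e-12)
  expect_true(all(imp$se >= 0))
  # oracle: se equals sd of per-tree importances / sqrt(ntree), rescaled
  raw <- fit$tree_importances
  expect_equal(
    imp$se,
    (apply(raw, 1, sd) / sqrt(25)) / sum(rowMeans(raw)),
    tolerance = 1e-12, ignore_attr = TRUE
  )
})

test_that("importance pruning applies the zero and SE rules", {
  mk <- function(imp, se) {
    structure(list(importance = tibble::tibble(
      feature = paste0("f", seq_along(imp)), importance = imp, se = se
    )), class = "bucket_result")
  }
  expect_identical(importance_prune(mk(c(0, 0.5, 0.2), c(0, 0.1, 0.3))),
                   "f2")
  expect_identical(importance_prune(mk(c(0.4, 0.6), c(0.1, 0.2))),
                   c("f1", "f2"))
  expect_warning(kept <- importance_prune(mk(c(0.1, 0.3), c(0.5, 0.9))),
                 "top")
  expect_identical(kept, "f2")
  # randomized element-wise filter oracle
  set.seed(37)
  for (i in 1:30) {
    imp <- round(runif(8, 0, 0.5), 2) * rbinom(8, 1, 0.7)
    se <- round(runif(8, 0, 0.4), 2)
    idx <- which(imp > 0 & se <= imp)
    keep_oracle <- if (length(idx)) paste0("f", idx) else character(0)
    r <- mk(imp, se)
    if (length(keep_oracle)) {
      expect_identical(importance_prune(r), keep_oracle)
    } else {
      expect_warning(expect_identical(importance_prune(r),
                                      paste0("f", which.max(imp))))
    }
  }
})

test_that("one separating feature converges immediately at accuracy 1", {
  tab <- separable_table(n_per_class = 40, p = 1, gap = 12, seed = 39)
  b <- iterate_build(tab, light_config(covariate_mode = "none",
                                       use_rfe = FALSE), seed = 1)
  expect_true(b$converged)
  expect_identical(nrow(b$log), 1L)
  expect_true(all(b$result$models$accuracy == 1))
})

test_that("feature sets shrink monotonically and the log is reproducible", {
  coh <- tiny_cohort(n_a = 12, n_b = 16, n_regions = 10,
                     effect_regions = 1:2, effect = 1.5, seed = 41)
  cfg <- light_config(accuracy_floor = 0.99, max_iterations = 4,
                      use_rfe = FALSE)
  b1 <- suppressWarnings(iterate_build(coh$table, cfg, seed = 5))
  expect_true(all(diff(b1$log$n_features) <= 0))
  b2 <- suppressWarnings(iterate_build(coh$table, cfg, seed = 5))
  expect_identical(b1$log, b2$log)
  expect_identical(b1$final_features, b2$final_features)
  expect_identical(b1$result$predictions, b2$result$predictions)
})

test_that("shuffled labels rarely clear the accuracy floor", {
  # null cohort: the floor condition should be met in well under 5% of runs
  coh <- tiny_cohort(n_a = 14, n_b = 14, n_regions = 5, seed = 43)
  cfg <- light_config(max_iterations = 1, use_rfe = FALSE,
                      floor_eval = "test")
  met <- 0L
  for (s in 1:200) {
    set.seed(s)
    shuffled <- coh$table
    shuffled$group <- sample(coh$table$group)
    b <- suppressWarnings(iterate_build(shuffled, cfg, seed = s))
    met <- met + as.integer(b$converged)
  }
  expect_lt(met, 10L)  # < 5% of 200
})
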