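#' Configuration of the nine-classifier bucket build
#'
#' Fixes every hyperparameter of the "bucket of models" so that a build is
#' reproducible from a config + seed alone. The nine classifiers are
#' k-nearest neighbours, linear-kernel SVM, decision tree, random forest,
#' AdaBoost over stumps, Gaussian naive Bayes, regularized quadratic
#' discriminant analysis, ridge logistic regression, and a one-hidden-layer
#' perceptron.
#'
#' @param accuracy_floor Per-model accuracy every (non-failed) model must
#'   reach for the iterative build to stop; default 0.69, the study's 69%
#'   inclusion threshold.
#' @param split_ratio Training fraction of the cohort split; default 0.5.
#' @param max_iterations Cap on prune/refit iterations; default 10.
#' @param floor_eval Where the accuracy floor is evaluated: `"train_cv"`
#'   (default; stratified cross-validation on the training set, avoiding the
#'   leakage of tuning on validation data) or `"test"` (the study-faithful
#'   variant: the held-out testing set).
#' @param covariate_mode `"residualize"` (default; features are replaced by
#'   their OLS residuals on age/sex/BMI fitted on the training rows),
#'   `"append"` (covariates join the feature set) or `"none"`.
#' @param use_rfe Run recursive feature elimination before the prune loop
#'   (default `TRUE`).
#' @param quartile_bin Recode features into training-set quartiles before
#'   modelling (default `FALSE`; an optional transform).
#' @param cv_folds Folds for all stratified cross-validation (default 5).
#' @param positive_class Positive class label (default `"CFS"`).
#' @param models Subset of model names to run (default all nine).
#' @param knn_k,svm_cost,forest_trees,boost_rounds,qda_reg,logistic_lambda,
#'   mlp_size,mlp_decay,mlp_maxit Per-model hyperparameters; defaults are
#'   k = 3 neighbours, unit-cost linear SVM, 100 trees, 50 boosting rounds,
#'   QDA shrinkage 0.5, logistic lambda 1/n (when `NULL`), and a 10-unit
#'   perceptron with weight decay 0.1 and 100 iterations.
#' @return An object of class `bucket_config`.
#' @export
bucket_config <- function(accuracy_floor = 0.69,
                          split_ratio = 0.5,
                          max_iterations = 10L,
                          floor_eval = c("train_cv", "test"),
                          covariate_mode = c("residualize", "append", "none"),
                          use_rfe = TRUE,
                          quartile_bin = FALSE,
                          cv_folds = 5L,
                          positive_class = "CFS",
                          models = NULL,
                          knn_k = 3L,
                          svm_cost = 1,
                          forest_trees = 100L,
                          boost_rounds = 50L,
                          qda_reg = 0.5,
                          logistic_lambda = NULL,
                          mlp_size = 10L,
                          mlp_decay = 0.1,
                          mlp_maxit = 100L) {
  stopifnot(accuracy_floor > 0, accuracy_floor < 1,
            split_ratio > 0, split_ratio < 1,
            max_iterations >= 1, cv_folds >= 2)
  cfg <- structure(
    list(accuracy_floor = accuracy_floor, split_ratio = split_ratio,
         max_iterations = as.integer(max_iterations),
         floor_eval = match.arg(floor_eval),
         covariate_mode = match.arg(covariate_mode),
         use_rfe = isTRUE(use_rfe), quartile_bin = isTRUE(quartile_bin),
         cv_folds = as.integer(cv_folds), positive_class = positive_class,
         knn_k = as.integer(knn_k), svm_cost = svm_cost,
         forest_trees = as.integer(forest_trees),
         boost_rounds = as.integer(boost_rounds), qda_reg = qda_reg,
         logistic_lambda = logistic_lambda,
         mlp_size = as.integer(mlp_size), mlp_decay = mlp_decay,
         mlp_maxit = as.integer(mlp_maxit)),
    class = "bucket_config"
  )
  all_models <- names(bucket_model_specs(cfg))
  cfg$models <- models %||% all_models
  stopifnot(all(cfg$models %in% all_models))
  cfg
}

#' @export
print.bucket_config <- function(x, ...) {
  cat(sprintf(
    "<bucket_config> %d models, floor %.0f%% (%s), split %.0f:%.0f, covariates: %s\n",
    length(x$models), 100 * x$accuracy_floor, x$floor_eval,
    100 * x$split_ratio, 100 * (1 - x$split_ratio), x$covariate_mode
  ))
  invisible(x)
}

#' Split a cohort into training and testing sets
#'
#' Disjoint, exhaustive row indices at the requested ratio, stratified by
#' group by default so both classes keep their proportions on each side of
#' the split.
#'
#' @param data Cohort table with a `group` column (or a factor via `labels`).
#' @param ratio Training fraction (default 0.5).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param stratify Stratify by class (default `TRUE`).
#' @param labels Optional explicit class factor overriding `data$group`.
#' @return List with integer vectors `train` and `test`.
#' @export
split_cohort <- function(data, ratio = 0.5, seed = 1L, stratify = TRUE,
                         labels = NULL) {
  y <- labels %||% data[["group"]]
  stopifnot(!is.null(y), ratio > 0, ratio < 1)
  y <- factor(y)
  n <- length(y)
  if (nlevels(droplevels(y)) < 2 || any(table(y) < 2)) {
    stop("each class needs at least 2 members to split", call. = FALSE)
  }
  train <- with_seed(seed, {
    if (stratify) {
      unlist(lapply(levels(y), function(cl) {
        idx <- which(y == cl)
        k <- max(1L, min(length(idx) - 1L, round(length(idx) * ratio)))
        sample(idx, k)
      }), use.names = FALSE)
    } else {
      sample(n, max(1L, min(n - 1L, round(n * ratio))))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Residualize features on nuisance covariates
#'
#' Replaces each feature by its residual from an ordinary-least-squares fit
#' on the covariates (with intercept), estimated on the training rows only
#' and applied to both splits, so group differences in age, sex or BMI
#' cannot masquerade as activation differences. Constant covariates are
#' dropped; if none remain the matrices pass through unchanged.
#'
#' @param train_x,test_x Subjects x features numeric matrices.
#' @param train_cov,test_cov Data frames of covariates (e.g. `age`, `sex`,
#'   `bmi`) aligned with the rows of the matrices; factors are expanded via
#'   `model.matrix`.
#' @return List with residualized `train` and `test` matrices.
#' @export
residualize_covariates <- function(train_x, test_x, train_cov, test_cov) {
  stopifnot(nrow(train_x) == nrow(train_cov),
            nrow(test_x) == nrow(test_cov))
  if (anyNA(train_cov) || anyNA(test_cov)) {
    stop("covariates must be complete for all subjects", call. = FALSE)
  }
  keep <- vapply(train_cov, function(v) length(unique(v)) > 1, logical(1))
  if (!any(keep)) {
    return(list(train = train_x, test = test_x))
  }
  cov_all <- rbind(as.data.frame(train_cov)[, keep, drop = FALSE],
                   as.data.frame(test_cov)[, keep, drop = FALSE])
  mm <- model.matrix(~ ., data = cov_all)
  mm_tr <- mm[seq_len(nrow(train_x)), , drop = FALSE]
  mm_te <- mm[-seq_len(nrow(train_x)), , drop = FALSE]
  if (qr(mm_tr)$rank < ncol(mm_tr)) {
    stop("covariate design is rank-deficient on the training rows",
         call. = FALSE)
  }
  beta <- lm.fit(mm_tr, train_x)$coefficients
  list(train = train_x - mm_tr %*% beta,
       test = test_x - mm_te %*% beta)
}

#' Recursive feature elimination on the training set
#'
#' Greedy backward elimination: features are ranked by the magnitude of
#' the standardized coefficient of a ridge-logistic model and the weakest
#' is removed one per step, down to a single feature. The ridge penalty is
#' chosen once by cross-validation on the full feature set and held fixed
#' along the elimination path: at many more features than subjects a
#' near-unpenalized coefficient ordering is dominated by sampling noise,
#' while the cross-validated shrinkage keeps the elimination order stable.
#' The retained subset size is the one maximizing stratified k-fold
#' cross-validated accuracy of the same model on the training set, with
#' ties resolved toward the *larger* subset.
#'
#' @param train_x Training features (subjects x features matrix).
#' @param train_y Training class factor (positive class = second level).
#' @param seed Integer seed (fold assignment and penalty selection).
#' @param folds Cross-validation folds (default 5).
#' @return List with `features` (retained names), `ranking` (elimination
#'   order, first eliminated first), `cv` (tibble: subset size, cv
#'   accuracy) and `lambda` (ridge penalty used).
#' @export
recursive_feature_elimination <- function(train_x, train_y, seed = 1L,
                                          folds = 5L) {
  stopifnot(ncol(train_x) >= 2)
  train_y <- factor(train_y)
  features <- colnames(train_x)
  y01 <- as.integer(train_y == positive_level(train_y))
  with_seed(seed, {
    lambda <- if (min(tabulate(y01 + 1L, 2L)) >= 8 && ncol(train_x) >= 2) {
      tryCatch(
        glmnet::cv.glmnet(train_x, y01, family = "binomial", alpha = 0,
                          nfolds = min(folds, 5L))$lambda.min,
        error = function(e) NULL
      )
    } else {
      NULL
    }
    fold <- stratified_folds(train_y, min(folds, min(table(train_y))))
    rank_fit <- function(cols) {
      fit_ridge_logistic(train_x[, cols, drop = FALSE], train_y,
                         lambda = lambda)
    }
    # subset sizes are scored with the prediction-grade (1/n) penalty; the
    # heavy shrinkage is used only to stabilize the elimination order
    cv_acc <- function(cols) {
      mean(vapply(unique(fold), function(f) {
        tr <- fold != f
        fit <- fit_ridge_logistic(train_x[tr, cols, drop = FALSE],
                                  train_y[tr])
        prob <- predict_ridge_logistic(fit,
                                       train_x[!tr, cols, drop = FALSE])
        mean(prob_to_class(prob, levels(train_y)) == train_y[!tr])
      }, numeric(1)))
    }
    sds <- apply(train_x, 2, sd)
    current <- features
    eliminated <- character(0)
    cv <- tibble::tibble(size = integer(), accuracy = numeric())
    while (length(current) >= 1) {
      cv <- dplyr::bind_rows(cv, tibble::tibble(
        size = length(current), accuracy = cv_acc(current)
      ))
      if (length(current) == 1) break
      b <- abs(coef_ridge_logistic(rank_fit(current), current)) *
        sds[current]
      b[is.na(b)] <- 0
      drop_f <- current[which.min(b)]
      eliminated <- c(eliminated, drop_f)
      current <- setdiff(current, drop_f)
    }
    best_size <- max(cv$size[cv$accuracy == max(cv$accuracy)])
    kept <- if (best_size == length(features)) {
      features
    } else {
      setdiff(features, eliminated[seq_len(length(features) - best_size)])
    }
    list(features = kept,
         ranking = c(eliminated, setdiff(features, eliminated)),
         cv = cv, lambda = lambda)
  })
}

#' Fit the bucket of models once
#'
#' Trains every configured classifier on identical training rows/features
#' and validates on the testing set. A model whose fit or prediction errors
#' is logged, marked failed, and the run continues. Random-forest
#' importances are mean decreases in impurity with per-tree standard errors;
#' the linear-SVM and logistic coefficient vectors are captured for
#' reporting.
#'
#' @param train_x,train_y Training features and class factor.
#' @param test_x,test_y Testing features and class factor.
#' @param config A [bucket_config()].
#' @param seed Integer seed.
#' @param iteration Iteration index recorded in the result.
#' @return An object of class `bucket_result`: tibble `models` (model,
#'   label, accuracy, failed), logical predictions matrix (models x test
#'   subjects, `TRUE` = positive class), `importance` tibble (feature,
#'   importance, se), `coefficients` tibble (feature, svm, logistic),
#'   `features_used`, `test_y`.
#' @export
fit_bucket <- function(train_x, train_y, test_x, test_y, config = bucket_config(),
                       seed = 1L, iteration = 1L) {
  stopifnot(ncol(train_x) >= 1, inherits(config, "bucket_config"))
  features <- colnames(train_x)
  train_y <- factor(train_y)
  test_y <- factor(test_y, levels = levels(train_y))
  specs <- bucket_model_specs(config)[config$models]
  if ("forest" %in% names(specs)) {
    # per-tree fit so impurity importances and their standard errors are
    # observable from the same forest that produces the predictions
    specs[["forest"]]$fit <- function(X, y, seed) {
      fit_forest(X, y, ntree = config$forest_trees, seed = seed,
                 per_tree = TRUE)
    }
  }
  fits <- vector("list", length(specs))
  names(fits) <- names(specs)
  pred <- matrix(NA, length(specs), nrow(test_x),
                 dimnames = list(names(specs), NULL))
  acc <- rep(NA_real_, length(specs))
  failed <- logical(length(specs))
  pos <- positive_level(train_y)
  with_seed(seed, {
    for (i in seq_along(specs)) {
      nm <- names(specs)[i]
      res <- tryCatch({
        fit <- specs[[i]]$fit(train_x, train_y, seed + i)
        prob <- specs[[i]]$predict(fit, test_x)
        list(fit = fit, prob = prob)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("model '%s' failed: %s", nm, conditionMessage(res)),
                call. = FALSE)
        failed[i] <- TRUE
        next
      }
      fits[[i]] <- res$fit
      cls <- prob_to_class(res$prob, levels(train_y))
      pred[i, ] <- cls == pos
      acc[i] <- mean(cls == test_y)
    }
  })
  importance <- if ("forest" %in% names(specs) &&
                    !failed[match("forest", names(specs))]) {
    forest_importance(fits[["forest"]])
  } else {
    tibble::tibble(feature = features, importance = NA_real_, se = NA_real_)
  }
  coefs <- tibble::tibble(
    feature = features,
    svm = if (!is.null(fits[["svm_linear"]])) {
      unname(coef_svm_linear(fits[["svm_linear"]], features))
    } else {
      NA_real_
    },
    logistic = if (!is.null(fits[["logistic"]])) {
      unname(coef_ridge_logistic(fits[["logistic"]], features))
    } else {
      NA_real_
    }
  )
  structure(
    list(
      iteration = as.integer(iteration),
      features_used = features,
      models = tibble::tibble(
        model = names(specs),
        label = vapply(specs, `[[`, character(1), "label"),
        accuracy = acc,
        failed = failed
      ),
      predictions = pred,
      importance = importance,
      coefficients = coefs,
      test_y = test_y,
      positive_class = pos
    ),
    class = "bucket_result"
  )
}

#' @export
print.bucket_result <- function(x, ...) {
  ok <- !x$models$failed
  cat(sprintf(
    "<bucket_result> iteration %d, %d features, %d/%d models fit, accuracy %.0f%%-%.0f%%\n",
    x$iteration, length(x$features_used), sum(ok), nrow(x$models),
    100 * min(x$models$accuracy[ok]), 100 * max(x$models$accuracy[ok])
  ))
  invisible(x)
}

#' Prune features by random-forest importance
#'
#' Drops every feature with zero importance, then every feature whose
#' importance standard error exceeds the importance itself. Surviving
#' feature order is preserved. If the rule would empty the feature list the
#' single top-importance feature is kept with a warning.
#'
#' @param result A `bucket_result` carrying forest importances.
#' @return Character vector of surviving feature names.
#' @export
#' @examples
#' r <- list(importance = tibble::tibble(
#'   feature = c("a", "b", "c"),
#'   importance = c(0, 0.5, 0.2), se = c(0, 0.1, 0.3)
#' ))
#' class(r) <- "bucket_result"
#' importance_prune(r)  # "b"
importance_prune <- function(result) {
  stopifnot(inherits(result, "bucket_result"))
  imp <- result$importance
  if (all(is.na(imp$importance))) {
    # forest failed: nothing to prune on
    return(imp$feature)
  }
  keep <- imp$importance > 0 & imp$se <= imp$importance
  if (!any(keep)) {
    warning("pruning would remove every feature; keeping the top one",
            call. = FALSE)
    return(imp$feature[which.max(imp$importance)])
  }
  imp$feature[keep]
}

# Per-model stratified CV accuracy on the training set (floor evaluation).
bucket_train_cv_accuracy <- function(train_x, train_y, config, seed) {
  specs <- bucket_model_specs(config)[config$models]
  with_seed(seed, {
    fold <- stratified_folds(train_y,
                             min(config$cv_folds, min(table(train_y))))
    acc <- matrix(NA_real_, length(specs), length(unique(fold)),
                  dimnames = list(names(specs), NULL))
    for (f in seq_along(unique(fold))) {
      ff <- unique(fold)[f]
      tr <- fold != ff
      for (i in seq_along(specs)) {
        a <- tryCatch({
          fit <- specs[[i]]$fit(train_x[tr, , drop = FALSE], train_y[tr],
                                seed + i)
          prob <- specs[[i]]$predict(fit, train_x[!tr, , drop = FALSE])
          mean(prob_to_class(prob, levels(train_y)) == train_y[!tr])
        }, error = function(e) NA_real_)
        acc[i, f] <- a
      }
    }
    rowMeans(acc)
  })
}

#' Iterative bucket build with importance-based feature elimination
#'
#' The full model-building loop: split the cohort, residualize covariates,
#' optionally quartile-bin, optionally run recursive feature elimination,
#' then repeat \{fit the nine-model bucket, check the per-model accuracy
#' floor, prune zero/unstable-importance features, refit\} until every
#' non-failed model clears the floor, no feature is pruned, or the
#' iteration cap is hit (in which case the result is flagged
#' non-converged).
#'
#' @param data Cohort/feature table with `group` plus region columns.
#' @param config A [bucket_config()].
#' @param seed Integer seed governing the split, folds and all model fits.
#' @param regions Feature columns (default [region_cols()]).
#' @return An object of class `bucket_build`: `final_features`, `result`
#'   (final `bucket_result`), `log` (per-iteration tibble), `converged`,
#'   `stop_reason`, `split`, `config`, `floor_accuracy` (per-model floor
#'   metric at the final iteration).
#' @export
iterate_build <- function(data, config = bucket_config(), seed = 1L,
                          regions = region_cols(data)) {
  stopifnot(length(regions) >= 1, "group" %in% names(data))
  y <- factor(data$group)
  if (!config$positive_class %in% levels(y)) {
    stop(sprintf("positive class '%s' absent from data$group",
                 config$positive_class), call. = FALSE)
  }
  y <- stats::relevel(y, ref = setdiff(levels(y), config$positive_class)[1])
  y <- factor(y, levels = c(setdiff(levels(y), config$positive_class)[1],
                            config$positive_class))
  split <- split_cohort(data, ratio = config$split_ratio, seed = seed,
                        labels = y)
  X <- region_matrix(data, regions)
  train_x <- X[split$train, , drop = FALSE]
  test_x <- X[split$test, , drop = FALSE]
  train_y <- y[split$train]
  test_y <- y[split$test]

  if (config$covariate_mode == "residualize") {
    covs <- intersect(c("age", "sex", "bmi"), names(data))
    if (length(covs)) {
      adj <- residualize_covariates(
        train_x, test_x,
        as.data.frame(data)[split$train, covs, drop = FALSE],
        as.data.frame(data)[split$test, covs, drop = FALSE]
      )
      train_x <- adj$train
      test_x <- adj$test
    }
  } else if (config$covariate_mode == "append") {
    covs <- intersect(c("age", "sex", "bmi"), names(data))
    if (length(covs)) {
      mm <- model.matrix(~ . - 1, data = as.data.frame(data)[, covs,
                                                             drop = FALSE])
      train_x <- cbind(train_x, mm[split$train, , drop = FALSE])
      test_x <- cbind(test_x, mm[split$test, , drop = FALSE])
    }
  }
  if (config$quartile_bin) {
    binned <- quartile_bin(train_x)
    train_x <- binned
    test_x <- quartile_bin(test_x, boundaries = attr(binned, "boundaries"))
  }

  features <- colnames(train_x)
  rfe <- NULL
  if (config$use_rfe && length(features) >= 2) {
    rfe <- recursive_feature_elimination(train_x, train_y, seed = seed + 1L,
                                         folds = config$cv_folds)
    features <- rfe$features
  }

  log <- tibble::tibble(iteration = integer(), n_features = integer(),
                        min_accuracy = numeric(), floor_met = logical(),
                        n_pruned = integer(), accuracies = list())
  result <- NULL
  floor_acc <- NULL
  stop_reason <- "max_iterations"
  for (it in seq_len(config$max_iterations)) {
    result <- fit_bucket(train_x[, features, drop = FALSE], train_y,
                         test_x[, features, drop = FALSE], test_y,
                         config = config, seed = seed + 100L * it,
                         iteration = it)
    floor_acc <- if (config$floor_eval == "train_cv") {
      bucket_train_cv_accuracy(train_x[, features, drop = FALSE], train_y,
                               config, seed = seed + 100L * it + 50L)
    } else {
      setNames(result$models$accuracy, result$models$model)
    }
    ok <- !is.na(floor_acc)
    floor_met <- any(ok) && all(floor_acc[ok] >= config$accuracy_floor)
    survivors <- importance_prune(result)
    n_pruned <- length(features) - length(survivors)
    log <- dplyr::bind_rows(log, tibble::tibble(
      iteration = it, n_features = length(features),
      min_accuracy = if (any(ok)) min(floor_acc[ok]) else NA_real_,
      floor_met = floor_met, n_pruned = n_pruned,
      accuracies = list(floor_acc)
    ))
    if (floor_met) {
      stop_reason <- "floor_met"
      break
    }
    if (n_pruned == 0) {
      stop_reason <- "no_prune"
      break
    }
    features <- survivors
  }
  structure(
    list(final_features = result$features_used, result = result, log = log,
         converged = stop_reason == "floor_met", stop_reason = stop_reason,
         rfe = rfe, split = split, config = config, seed = seed,
         floor_accuracy = floor_acc, labels = y),
    class = "bucket_build"
  )
}

#' @export
print.bucket_build <- function(x, ...) {
  cat(sprintf(
    "<bucket_build> %d iteration(s), %d final feature(s), %s (%s)\n",
    nrow(x$log), length(x$final_features),
    if (x$converged) "converged" else "not converged", x$stop_reason
  ))
  invisible(x)
}
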