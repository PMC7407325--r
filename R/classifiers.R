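# The nine classifiers behind fit_bucket(), each exposed through a uniform
# internal interface: spec$fit(X, y, seed) -> fitted object,
# spec$predict(fit, X) -> probability of the positive class (second factor
# level). Predicted class is positive iff prob >= 0.5, so probability ties
# break toward the positive class.
#
# Buy where a package exists: kNN (class), linear SVM (e1071), decision tree
# (rpart), random forest (randomForest), naive Bayes (e1071), ridge logistic
# (glmnet), multilayer perceptron (nnet). AdaBoost (no boosting package in
# the stack) and regularized QDA (MASS::qda cannot handle more features than
# per-class observations) are implemented here.

positive_level <- function(y) levels(y)[2L]

prob_to_class <- function(prob, y_levels) {
  factor(ifelse(prob >= 0.5, y_levels[2L], y_levels[1L]), levels = y_levels)
}

# ---- weighted decision stump (weak learner for AdaBoost) --------------------

# Best single-feature threshold split under observation weights. For each
# feature the weighted 0/1 error of every threshold (midpoints between
# sorted values) and both polarities is scanned with cumulative sums.
fit_stump <- function(X, y01, w) {
  w <- w / sum(w)
  w_pos <- sum(w[y01 == 1])
  # Trivial stumps: predict all negative (err = w_pos, polarity 1 with
  # threshold Inf) or all positive (err = 1 - w_pos, polarity -1).
  best <- if (w_pos <= 1 - w_pos) {
    list(err = w_pos, feature = 1L, threshold = Inf, polarity = 1)
  } else {
    list(err = 1 - w_pos, feature = 1L, threshold = Inf, polarity = -1)
  }
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    o <- order(x)
    xs <- x[o]
    ws <- w[o]
    ys <- y01[o]
    # err_rp[i]: rule "predict 1 for x > cut after position i" misclassifies
    # positives at or below the cut plus negatives above it.
    cum_pos <- cumsum(ws * ys)
    cum_neg <- cumsum(ws * (1 - ys))
    err_rp <- cum_pos + ((1 - w_pos) - cum_neg)
    err_lp <- 1 - err_rp
    cand <- which(xs != c(xs[-1], Inf))  # cut between distinct values only
    if (!length(cand)) next
    e1 <- err_rp[cand]
    e2 <- err_lp[cand]
    i1 <- which.min(e1)
    i2 <- which.min(e2)
    if (e1[i1] < best$err) {
      best <- list(err = e1[i1], feature = j,
                   threshold = (xs[cand[i1]] + xs[cand[i1] + 1]) / 2,
                   polarity = 1)
    }
    if (e2[i2] < best$err) {
      best <- list(err = e2[i2], feature = j,
                   threshold = (xs[cand[i2]] + xs[cand[i2] + 1]) / 2,
                   polarity = -1)
    }
  }
  best
}

predict_stump <- function(stump, X) {
  x <- X[, stump$feature]
  if (stump$polarity == 1) {
    as.integer(x > stump$threshold)
  } else {
    as.integer(x <= stump$threshold)
  }
}

# Discrete AdaBoost (two-class SAMME) over depth-1 stumps.
fit_adaboost <- function(X, y01, rounds = 50) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  stumps <- list()
  alphas <- numeric(0)
  for (m in seq_len(rounds)) {
    stump <- fit_stump(X, y01, w)
    pred <- predict_stump(stump, X)
    err <- sum(w * (pred != y01))
    if (err >= 0.5) break
    alpha <- 0.5 * log((1 - err) / max(err, 1e-10))
    stumps[[length(stumps) + 1]] <- stump
    alphas <- c(alphas, alpha)
    if (err <= 1e-10) break
    w <- w * exp(alpha * ifelse(pred != y01, 1, -1))
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas)
}

predict_adaboost <- function(fit, X) {
  if (length(fit$stumps) == 0) {
    return(rep(0.5, nrow(X)))
  }
  score <- rowSums(vapply(seq_along(fit$stumps), function(m) {
    fit$alphas[m] * (2 * predict_stump(fit$stumps[[m]], X) - 1)
  }, numeric(nrow(X))))
  # Map the margin to (0,1); only the sign (and the 0 -> positive tie-break
  # via >= 0.5) matters for classification.
  1 / (1 + exp(-2 * score))
}

# ---- regularized quadratic discriminant -------------------------------------

# Gaussian QDA with per-class covariance shrunk toward a scaled identity,
# Sigma_reg = (1 - r) Sigma + r (tr(Sigma)/p) I, so it stays well-defined
# when a class has fewer observations than features.
fit_rqda <- function(X, y, reg = 0.1) {
  p <- ncol(X)
  classes <- levels(y)
  fits <- lapply(classes, function(cl) {
    Xc <- X[y == cl, , drop = FALSE]
    mu <- colMeans(Xc)
    S <- if (nrow(Xc) > 1) stats::cov(Xc) else diag(0, p)
    tr <- sum(diag(S)) / p
    if (tr <= 0) tr <- 1
    Sr <- (1 - reg) * S + reg * tr * diag(p)
    ch <- chol(Sr)
    list(mu = mu, chol = ch, logdet = 2 * sum(log(diag(ch))),
         prior = log(nrow(Xc) / nrow(X)))
  })
  names(fits) <- classes
  list(classes = classes, fits = fits)
}

predict_rqda <- function(fit, X) {
  scores <- vapply(fit$fits, function(f) {
    D <- sweep(X, 2, f$mu)
    z <- backsolve(f$chol, t(D), transpose = TRUE)
    -0.5 * colSums(z^2) - 0.5 * f$logdet + f$prior
  }, numeric(nrow(X)))
  if (nrow(X) == 1) scores <- matrix(scores, nrow = 1)
  # posterior probability of the positive (second) class
  1 / (1 + exp(scores[, 1] - scores[, 2]))
}

# ---- model specs ------------------------------------------------------------

# Each spec: list(label, fit(X, y, seed, cfg), predict(fit, X)).
bucket_model_specs <- function(cfg) {
  list(
    knn = list(
      label = "K-Nearest Neighbors",
      fit = function(X, y, seed) list(X = X, y = y, k = cfg$knn_k),
      predict = function(fit, X) {
        pr <- class::knn(fit$X, X, fit$y, k = min(fit$k, nrow(fit$X)),
                         prob = TRUE)
        p_win <- attr(pr, "prob")
        ifelse(pr == positive_level(fit$y), p_win, 1 - p_win)
      }
    ),
    svm_linear = list(
      label = "Linear SVM",
      fit = function(X, y, seed) fit_svm_linear(X, y, cost = cfg$svm_cost),
      predict = predict_svm_linear
    ),
    tree = list(
      label = "Decision Tree",
      fit = function(X, y, seed) {
        # default check.names mangling is applied identically at fit and
        # predict time, so merged feature names ("a+b") are safe
        df <- data.frame(.y = y, X)
        with_seed(seed, rpart::rpart(
          .y ~ ., df, method = "class",
          control = rpart::rpart.control(cp = 0, minsplit = 2, xval = 0)
        ))
      },
      predict = function(fit, X) {
        pr <- predict(fit, data.frame(X), type = "prob")
        pr[, ncol(pr)]
      }
    ),
    forest = list(
      label = "Random Forest",
      fit = function(X, y, seed) {
        fit_forest(X, y, ntree = cfg$forest_trees, seed = seed,
                   per_tree = FALSE)
      },
      predict = predict_forest
    ),
    adaboost = list(
      label = "AdaBoost",
      fit = function(X, y, seed) {
        fit_adaboost(X, as.integer(y == positive_level(y)),
                     rounds = cfg$boost_rounds)
      },
      predict = function(fit, X) predict_adaboost(fit, X)
    ),
    naive_bayes = list(
      label = "Naive Bayes",
      fit = function(X, y, seed) e1071::naiveBayes(X, y),
      predict = function(fit, X) {
        pr <- predict(fit, X, type = "raw")
        pr[, ncol(pr)]
      }
    ),
    qda = list(
      label = "Quadratic Discriminant Analysis",
      fit = function(X, y, seed) fit_rqda(X, y, reg = cfg$qda_reg),
      predict = predict_rqda
    ),
    logistic = list(
      label = "Logistic Regression",
      fit = function(X, y, seed) fit_ridge_logistic(X, y, cfg$logistic_lambda),
      predict = predict_ridge_logistic
    ),
    mlp = list(
      label = "Neural Net",
      fit = function(X, y, seed) {
        y01 <- as.integer(y == positive_level(y))
        with_seed(seed, nnet::nnet(
          X, y01, size = cfg$mlp_size, decay = cfg$mlp_decay,
          maxit = cfg$mlp_maxit, entropy = TRUE, trace = FALSE,
          MaxNWts = 100000
        ))
      },
      predict = function(fit, X) as.numeric(predict(fit, X))
    )
  )
}

# Random forest fitted as seeded single-tree forests so per-tree impurity
# importances are observable; prediction is the majority vote over trees
# (probability = vote fraction). With per_tree = FALSE a single
# randomForest call is used (faster; no importance standard errors).
fit_forest <- function(X, y, ntree, seed, per_tree = TRUE) {
  if (!per_tree) {
    return(list(
      per_tree = FALSE,
      rf = with_seed(seed, randomForest::randomForest(X, y, ntree = ntree)),
      levels = levels(y)
    ))
  }
  trees <- with_seed(seed, {
    lapply(seq_len(ntree), function(i) {
      randomForest::randomForest(X, y, ntree = 1)
    })
  })
  imp <- vapply(trees, function(tr) {
    randomForest::importance(tr, type = 2)[, 1]
  }, numeric(ncol(X)))
  if (ncol(X) == 1) imp <- matrix(imp, nrow = 1)
  list(per_tree = TRUE, trees = trees, tree_importances = imp,
       levels = levels(y))
}

predict_forest <- function(fit, X) {
  if (isFALSE(fit$per_tree)) {
    pr <- predict(fit$rf, X, type = "prob")
    return(pr[, ncol(pr)])
  }
  votes <- vapply(fit$trees, function(tr) {
    predict(tr, X) == fit$levels[2]
  }, logical(nrow(X)))
  if (nrow(X) == 1) votes <- matrix(votes, nrow = 1)
  rowMeans(votes)
}

# Mean decrease in impurity per feature with its standard error
# (per-tree SD / sqrt(ntree)), normalized so the means sum to 1.
forest_importance <- function(fit) {
  stopifnot(isTRUE(fit$per_tree))
  imp <- fit$tree_importances
  m <- rowMeans(imp)
  se <- apply(imp, 1, sd) / sqrt(ncol(imp))
  tot <- sum(m)
  if (tot > 0) {
    se <- se / tot
    m <- m / tot
  }
  tibble::tibble(feature = rownames(imp) %||% paste0("f", seq_along(m)),
                 importance = m, se = se)
}

# Ridge-penalized logistic regression (the common default-regularized
# logistic model); lambda defaults to 1/n. Falls back to an unpenalized
# glm fit for a single feature, where glmnet does not apply.
fit_ridge_logistic <- function(X, y, lambda = NULL) {
  y01 <- as.integer(y == positive_level(y))
  lambda <- lambda %||% (1 / nrow(X))
  # glmnet needs >= 2 features and >= 2 observations per class
  if (ncol(X) >= 2 && min(tabulate(y01 + 1L, 2L)) >= 2) {
    fit <- glmnet::glmnet(X, y01, family = "binomial", alpha = 0,
                          lambda = lambda)
    list(engine = "glmnet", fit = fit, lambda = lambda,
         features = colnames(X))
  } else {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, X), y01, family = stats::binomial())
    )
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0  # rank-deficient fit: unidentified terms drop out
    list(engine = "glm", coef = cf, features = colnames(X))
  }
}

predict_ridge_logistic <- function(fit, X) {
  if (fit$engine == "glmnet") {
    as.numeric(predict(fit$fit, X, type = "response"))
  } else {
    eta <- drop(cbind(1, X) %*% fit$coef)
    1 / (1 + exp(-eta))
  }
}

coef_ridge_logistic <- function(fit, features) {
  if (fit$engine == "glmnet") {
    b <- as.matrix(stats::coef(fit$fit))[, 1]
    setNames(b[features], features)
  } else {
    b <- setNames(fit$coef[-1], fit$features)
    setNames(b[features], features)
  }
}

# Linear support-vector machine with a weight vector explicitly oriented so
# that a positive decision score favours the positive (second) factor
# level; e1071's internal sign convention is calibrated against its own
# class predictions on the training data.
fit_svm_linear <- function(X, y, cost = 1) {
  model <- e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(model$coefs) %*% model$SV)
  b <- -model$rho
  score <- drop(X %*% w) + b
  pred <- predict(model, X)
  pos <- positive_level(y)
  agree <- sum((score > 0) == (pred == pos))
  flip <- agree < nrow(X) / 2
  if (flip) {
    w <- -w
    b <- -b
  }
  list(model = model, w = w, b = b, features = colnames(X))
}

predict_svm_linear <- function(fit, X) {
  score <- drop(X %*% fit$w) + fit$b
  1 / (1 + exp(-score))
}

coef_svm_linear <- function(fit, features) {
  setNames(fit$w[features], features)
}
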