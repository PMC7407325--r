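# two-pass textbook sample correlation, the independent oracle
cor_oracle <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

test_that("pearson_matrix equals the textbook formula to 1e-12", {
  set.seed(23)
  for (i in 1:20) {
    X <- matrix(rnorm(12 * 5), 12, 5,
                dimnames = list(NULL, letters[1:5]))
    R <- pearson_matrix(X)
    expect_identical(dim(R), c(5L, 5L))
    expect_equal(unname(diag(R)), rep(1, 5))
    expect_equal(R, t(R), tolerance = 1e-12)
    for (a in 1:4) {
      for (b in (a + 1):5) {
        expect_equal(R[a, b], cor_oracle(X[, a], X[, b]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("hand example: (1,2,3) vs (1,2,4) correlates at ~0.982", {
  R <- pearson_matrix(cbind(a = c(1, 2, 3), b = c(1, 2, 4)))
  expect_equal(R["a", "b"], 3 / sqrt(2 * 14 / 3), tolerance = 1e-12)
  expect_equal(R["a", "b"], 0.982, tolerance = 1e-3)
})

test_that("duplicated columns correlate at exactly 1", {
  x <- rnorm(10)
  R <- pearson_matrix(cbind(a = x, b = x))
  expect_equal(R["a", "b"], 1, tolerance = 1e-12)
})

test_that("constant columns give missing entries, not errors", {
  X <- cbind(a = rnorm(8), b = rep(2, 8))
  R <- pearson_matrix(X)
  expect_true(is.na(R["a", "b"]))
  expect_identical(attr(R, "constant_cols"), "b")
})

test_that("pearson_matrix wants at least 3 rows and 117 features give 117x117", {
  expect_error(pearson_matrix(matrix(1:4, 2, 2)), "3 rows")
  coh <- tiny_cohort(n_a = 4, n_b = 5, n_regions = 117, seed = 3,
                     grid = c(12, 12, 12))
  expect_identical(dim(pearson_matrix(coh$table)), c(117L, 117L))
})

test_that("a feature and its negation are flagged by the absolute-value rule", {
  set.seed(5)
  x <- rnorm(10)
  X <- cbind(a = x, b = -x, c = rnorm(10))
  rep <- flag_collinear_pairs(X[1:5, ], X[6:10, ])
  pair <- dplyr::distinct(rep$flagged_pairs, feature_i, feature_j)
  expect_true(any(pair$feature_i == "a" & pair$feature_j == "b"))
})

test_that("flagging matches a brute-force pairwise check across datasets", {
  set.seed(31)
  for (i in 1:25) {
    n <- 12
    base <- matrix(rnorm(n * 10), n, 10)
    # induce some near-collinear pairs
    base[, 2] <- base[, 1] + rnorm(n, sd = 0.05)
    base[, 7] <- -base[, 6] + rnorm(n, sd = 0.3)
    colnames(base) <- sprintf("f%02d", 1:10)
    tr <- base[1:6, ]
    te <- base[7:12, ]
    rep <- flag_collinear_pairs(tr, te, threshold = 0.9)
    mats <- list(train = suppressWarnings(cor(tr)),
                 test = suppressWarnings(cor(te)),
                 combined = suppressWarnings(cor(base)))
    brute <- character(0)
    for (a in 1:9) {
      for (b in (a + 1):10) {
        if (any(vapply(mats, function(M) {
          !is.na(M[a, b]) && abs(M[a, b]) >= 0.9
        }, logical(1)))) {
          brute <- c(brute, paste(colnames(base)[a], colnames(base)[b]))
        }
      }
    }
    got <- unique(paste(rep$flagged_pairs$feature_i,
                        rep$flagged_pairs$feature_j))
    expect_setequal(got, brute)
  }
})

test_that("merging is the identity when nothing is flagged", {
  set.seed(7)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, letters[1:4]))
  rep <- flag_collinear_pairs(X[1:5, ], X[6:10, ])
  expect_identical(nrow(rep$flagged_pairs), 0L)
  out <- merge_collinear(X, rep)
  expect_identical(out$X, X)
})

test_that("duplicated columns merge into their sum and reach a fixed point", {
  set.seed(9)
  x <- round(runif(12, 0, 50))
  X <- cbind(a = x, b = x, c = round(runif(12, 0, 50)))
  rep <- flag_collinear_pairs(X[1:6, ], X[7:12, ])
  out <- merge_collinear(X, rep)
  expect_true("a+b" %in% colnames(out$X))
  expect_identical(out$X[, "a+b"], x + x)
  # total count mass conserved
  expect_identical(sum(out$X), sum(X))
  # fixed point: re-screening the output flags nothing
  rep2 <- flag_collinear_pairs(out$X[1:6, ], out$X[7:12, ])
  expect_identical(nrow(rep2$flagged_pairs), 0L)
  # idempotence
  out2 <- merge_collinear(out$X, rep2)
  expect_identical(out2$X, out$X)
})

test_that("screen_features applies identical merges to both splits", {
  set.seed(13)
  x <- rnorm(20)
  X <- cbind(a = x, b = x + rnorm(20, sd = 0.01), c = rnorm(20))
  sc <- screen_features(X[1:10, ], X[11:20, ])
  expect_identical(colnames(sc$train), colnames(sc$test))
  expect_identical(nrow(sc$report$flagged_pairs), 0L)
  expect_true(all(c("a", "b") %in% unlist(sc$report$merges$members)) ||
                identical(colnames(sc$train), colnames(X)))
})

test_that("quartile coding maps one value per quartile to its code", {
  codes <- quartile_bin(matrix(c(1, 2, 3, 4), ncol = 1))
  expect_identical(as.vector(codes), 1:4)
})

test_that("degenerate all-equal columns code as 1 with a warning", {
  X <- cbind(a = rep(3, 6), b = 1:6)
  expect_warning(codes <- quartile_bin(X), "degenerate")
  expect_true(all(codes[, "a"] == 1L))
})

test_that("quartile codes match a sort-and-split brute force", {
  set.seed(17)
  for (i in 1:30) {
    x <- rnorm(20)
    codes <- quartile_bin(matrix(x, ncol = 1))
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    oracle <- 1L + (x > q[1]) + (x > q[2]) + (x > q[3])
    expect_identical(as.vector(codes), as.integer(oracle))
    expect_true(all(codes %in% 1:4))
  }
})

test_that("persisted boundaries code a held-out set on training quartiles", {
  set.seed(19)
  tr <- matrix(rnorm(40), ncol = 2, dimnames = list(NULL, c("a", "b")))
  te <- matrix(rnorm(10), ncol = 2, dimnames = list(NULL, c("a", "b")))
  ctr <- quartile_bin(tr)
  cte <- quartile_bin(te, boundaries = attr(ctr, "boundaries"))
  q <- attr(ctr, "boundaries")
  oracle <- 1L + (te[, 1] > q["q25", "a"]) + (te[, 1] > q["q50", "a"]) +
    (te[, 1] > q["q75", "a"])
  expect_identical(cte[, "a"], as.integer(oracle))
})
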