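test_that("zscore uses the population sd and flags constant columns", {
  z <- zscore(cbind(a = c(1, 2, 3), b = c(5, 5, 5)))
  expect_equal(z$values[, "a"], c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-9)
  expect_equal(z$values[, "b"], c(0, 0, 0))
  expect_true(z$constant["b"])
  expect_false(z$constant["a"])

  withr::with_seed(2, {
    x <- matrix(rnorm(500), 50, 10)
  })
  zz <- zscore(x)
  expect_lt(max(abs(colMeans(zz$values))), 1e-9)
  expect_lt(max(abs(apply(zz$values, 2, function(v) sqrt(mean(v^2))) - 1)), 1e-9)
  # idempotence: standardizing standardized data changes nothing
  expect_equal(zscore(zz$values)$values, zz$values, tolerance = 1e-9)

  expect_error(zscore(matrix(1, 1, 3)), "at least 2")
})

test_that("pearson matrix handles exact linear maps and degenerate columns", {
  x <- seq_len(20)
  m <- cbind(x = x, up = 2 * x + 1, down = -x, const = rep(3, 20))
  r <- pearson_matrix(m)
  expect_equal(r["x", "up"], 1)
  expect_equal(r["x", "down"], -1)
  expect_equal(r["x", "const"], 0)     # undefined -> 0, flagged
  expect_true(attr(r, "constant")["const"])
  expect_equal(diag(r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(r, t(r), ignore_attr = TRUE)
  expect_true(all(r >= -1 & r <= 1))

  # affine invariance with positive slope
  r2 <- pearson_matrix(sweep(m[, 1:3], 2, c(2, 3, 0.5), `*`) + 7)
  expect_equal(r2, r[1:3, 1:3], tolerance = 1e-12, ignore_attr = TRUE)

  # independent columns: |r| stays small
  withr::with_seed(11, {
    ind <- matrix(rnorm(2000), 1000, 2)
  })
  expect_lt(abs(pearson_matrix(ind)[1, 2]), 0.1)
})

test_that("error metrics reproduce the hand-worked example", {
  em <- error_metrics(c(10, 20), c(11, 19))
  expect_equal(em$mape_pct, 7.5)
  expect_equal(em$rmse, 1)
  expect_equal(em$r2, 0.96)  # 1 - 2 / sum((x - mean(y))^2), mean(y) = 15

  perfect <- error_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$mape_pct, 0)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$r2, 1)

  # n = 1: MAPE and RMSE fine; with the system-mean centring the R2
  # denominator equals the numerator, so R2 collapses to 0
  single <- error_metrics(10, 12)
  expect_equal(single$mape_pct, 20)
  expect_equal(single$rmse, 2)
  expect_equal(single$r2, 0)
  # the denominator only degenerates when reference and system agree
  degen <- error_metrics(10, 10)
  expect_true(degen$r2_degenerate)
  expect_true(is.na(degen$r2))

  expect_error(error_metrics(c(0, 1), c(1, 1)), "zero")
  expect_error(error_metrics(1:3, 1:4), "equal length")
})

test_that("cross-validation is deterministic and solves the separable case", {
  cd <- cluster_data(n = 200, sep = 10, seed = 1)
  xs <- zscore(cd$x)
  for (m in c("cart", "rf", "svm", "nb", "xgboost")) {
    rep1 <- crossval_classify(xs, cd$y, m, seed = 3)
    expect_gte(rep1$accuracy_pct, 99)
    expect_length(rep1$fold_accuracies, 10)
    expect_true(all(rep1$fold_accuracies >= 0 & rep1$fold_accuracies <= 100))
  }
  r1 <- crossval_classify(xs, cd$y, "xgboost", seed = 5)
  r2 <- crossval_classify(xs, cd$y, "xgboost", seed = 5)
  expect_identical(r1$fold_accuracies, r2$fold_accuracies)
  expect_identical(r1$importance, r2$importance)

  expect_error(crossval_classify(xs, rep("a", 200), "svm"), "2 classes")
  expect_error(crossval_classify(cd$x[1:10, ], cd$y[1:10], "svm"), "at least")
})

test_that("permuted labels drive accuracy to chance", {
  cd <- cluster_data(n = 200, sep = 10, seed = 2)
  withr::with_seed(9, {
    ynull <- sample(cd$y)
  })
  r <- crossval_classify(zscore(cd$x), ynull, "xgboost", seed = 7)
  expect_gte(r$accuracy_pct, 40)
  expect_lte(r$accuracy_pct, 60)
})

test_that("feature importances are normalized and rank the informative trait first", {
  withr::with_seed(4, {
    x <- matrix(rnorm(200 * 25), 200, 25)
    colnames(x) <- trait_names()
    y <- rep(c("filled", "unfilled"), each = 100)
    x[y == "unfilled", "h"] <- x[y == "unfilled", "h"] + 4  # only thickness differs
  })
  xs <- zscore(x)
  for (m in c("cart", "rf", "xgboost")) {
    r <- crossval_classify(xs, y, m, seed = 2)
    fi <- feature_importance(r)
    expect_equal(fi$trait[1], "h")
    expect_equal(sum(fi$weight), 1, tolerance = 1e-6)
    expect_true(all(fi$weight >= 0))
    expect_true(all(diff(fi$weight) <= 1e-12))
    expect_true(fi$above_threshold[1])
  }
  r_svm <- crossval_classify(xs, y, "svm", seed = 2)
  expect_error(feature_importance(r_svm), "does not expose")
})

test_that("pure-noise features never dominate the importance ranking", {
  mx <- vapply(1:10, function(s) {
    withr::with_seed(100 + s, {
      x <- matrix(rnorm(120 * 25), 120, 25)
      colnames(x) <- trait_names()
      y <- rep(c("a", "b"), each = 60)
    })
    r <- crossval_classify(zscore(x), y, "xgboost", seed = s)
    max(r$importance$weight)
  }, numeric(1))
  expect_lt(mean(mx), 3 / 25)
})

test_that("the back-propagation network learns the separable case", {
  cd <- cluster_data(n = 120, sep = 10, seed = 3)
  r <- crossval_classify(zscore(cd$x), cd$y, "bp", seed = 1, folds = 5)
  expect_gte(r$accuracy_pct, 99)
  r2 <- crossval_classify(zscore(cd$x), cd$y, "bp", seed = 1, folds = 5)
  expect_identical(r$fold_accuracies, r2$fold_accuracies)
})

test_that("macro precision/recall/F1 come from the pooled confusion matrix", {
  cd <- cluster_data(n = 60, sep = 10, seed = 6)
  r <- crossval_classify(zscore(cd$x), cd$y, "nb", seed = 2, folds = 5)
  conf <- r$confusion
  tp <- diag(conf)
  prec <- mean(tp / colSums(conf))
  rec <- mean(tp / rowSums(conf))
  expect_equal(r$precision_pct, prec * 100, tolerance = 1e-9)
  expect_equal(r$recall, rec, tolerance = 1e-9)
  expect_equal(r$f1, mean(2 * (tp / colSums(conf)) * (tp / rowSums(conf)) /
                            ((tp / colSums(conf)) + (tp / rowSums(conf)))),
               tolerance = 1e-9)
})
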