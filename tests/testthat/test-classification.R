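test_that("roc_auc equals the exhaustive pair-counting oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(1, 1, 0, 0)), 0)
  expect_equal(roc_auc(c(0.9, 0.1, 0.8, 0.2), c(1, 0, 0, 1)), 0.75)
  set.seed(17)
  for (rep in seq_len(500)) {
    n <- sample(4:12, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(roc_auc(scores, labels), pairwise_auc(scores, labels))
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("roc_auc is monotone-invariant and label-swap antisymmetric", {
  set.seed(23)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.5)
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels), a)
  expect_equal(roc_auc(rank(scores), labels), a)
  expect_equal(roc_auc(scores, 1 - labels), 1 - a)
})

test_that("AUC bootstrap interval is seeded, degenerate on perfect separation, and near-nominal width", {
  scores <- c(rnorm(40, 0), rnorm(40, 5))
  labels <- rep(0:1, each = 40)
  ci <- auc_bootstrap_ci(scores, labels, B = 200, seed = 1)
  expect_equal(ci[1], 1)
  expect_equal(ci[2], 1)
  set.seed(2)
  s50 <- rnorm(50)
  l50 <- rep(0:1, 25)
  expect_identical(as.numeric(auc_bootstrap_ci(s50, l50, B = 150, seed = 3)),
                   as.numeric(auc_bootstrap_ci(s50, l50, B = 150, seed = 3)))

  set.seed(9)
  n <- 1000
  s <- rnorm(2 * n)
  l <- rep(0:1, n)
  ci0 <- auc_bootstrap_ci(s, l, B = 400, seed = 5)
  hm_se <- sqrt(1 / 12 * (1 / n + 1 / n))  # Hanley-McNeil at AUC 0.5
  width <- ci0[2] - ci0[1]
  expect_lt(width, 1.5 * 2 * 1.96 * hm_se)
  expect_gt(width, 2 * 1.96 * hm_se / 1.5)
})

test_that("kNN cross-validation separates blobs, is seeded, and guards k", {
  set.seed(31)
  n <- 200
  X <- rbind(matrix(rnorm(n * 5, 0), ncol = 5), matrix(rnorm(n * 5, 4), ncol = 5))
  y <- rep(0:1, each = n)
  res <- knn_cv(as.data.frame(X), y, k = 5, B = 150, seed = 2)
  expect_gt(res$auc, 0.99)
  expect_true(res$ci[1] <= res$auc && res$auc <= res$ci[2])
  res2 <- knn_cv(as.data.frame(X), y, k = 5, B = 150, seed = 2)
  expect_identical(res$scores, res2$scores)
  expect_identical(res$fold, res2$fold)
  expect_error(knn_cv(as.data.frame(X[1:24, ]), y[c(1:12, 201:212)], k = 15),
               "too large")
})

test_that("PLS-DA recovers a single-feature signal with positive sign", {
  set.seed(41)
  n <- 150
  X <- data.frame(bulges = rnorm(2 * n), loops = rnorm(2 * n),
                  junctions = rnorm(2 * n), helices = rnorm(2 * n),
                  bonds = c(rnorm(n, 0), rnorm(n, 2)))
  y <- rep(0:1, each = n)
  res <- plsda_cv(X, y, n_components = 2, B = 150, seed = 6)
  imp <- res$importances
  expect_equal(names(which.max(abs(imp))), "bonds")
  expect_gt(imp["bonds"], 0)
  expect_gt(res$auc, 0.85)
  expect_length(imp, 5L)
  expect_length(res$vip, 5L)
  expect_s3_class(tidy(res), "tbl_df")
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(plot_importances(res), "ggplot")
})

test_that("both classifiers sit inside the permutation null band on exchangeable classes", {
  set.seed(51)
  X <- as.data.frame(matrix(rnorm(160 * 5), ncol = 5))
  names(X) <- c("bulges", "loops", "junctions", "helices", "bonds")
  y <- rep(0:1, each = 80)
  for (res in list(knn_cv(X, y, B = 150, seed = 7),
                   plsda_cv(X, y, B = 150, seed = 7))) {
    null_auc <- vapply(seq_len(200), function(b) {
      set.seed(1000 + b)
      roc_auc(res$scores, sample(res$labels))
    }, numeric(1))
    band <- quantile(null_auc, c(0.025, 0.975))
    expect_gte(res$auc, band[1])
    expect_lte(res$auc, band[2])
  }
})
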