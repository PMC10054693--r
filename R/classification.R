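.check_binary <- function(labels) {
  labels <- as.integer(labels)
  if (any(is.na(labels)) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be binary 0/1", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  labels
}

#' Area under the ROC curve
#'
#' Computed in the rank (Mann–Whitney) form: the probability that a random
#' positive scores above a random negative, with tied scores contributing
#' 1/2 per tied pair. Equals U / (n1 * n0).
#'
#' @param scores Numeric classifier scores, higher meaning "more positive".
#' @param labels Binary 0/1 labels, same length.
#' @return A single number in `[0, 1]`.
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), !any(is.na(scores)))
  labels <- .check_binary(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  r <- rank(scores)  # average ranks give the 1/2-per-tie convention
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap confidence interval for an ROC AUC
#'
#' Resamples the pooled (score, label) pairs with replacement `B` times and
#' returns the 2.5%/97.5% percentiles of the resampled AUCs. Resamples that
#' lose one class entirely are redrawn (and counted in the `redraws`
#' attribute).
#'
#' @param scores,labels As in [roc_auc()].
#' @param B Number of bootstrap replicates (at least 100).
#' @param seed Seed.
#' @return Numeric length-2 vector `c(lo, hi)`.
#' @export
auc_bootstrap_ci <- function(scores, labels, B = 1000L, seed = 1L) {
  stopifnot(B >= 100L)
  labels <- .check_binary(labels)
  set.seed(seed)
  n <- length(scores)
  redraws <- 0L
  reps <- vapply(seq_len(B), function(b) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
      redraws <<- redraws + 1L
    }
    roc_auc(scores[idx], labels[idx])
  }, numeric(1))
  ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE)
  attr(ci, "redraws") <- redraws
  ci
}

# Deterministic stratified fold assignment: within each class, indices are
# shuffled under the seed and dealt round-robin into the folds.
.stratified_folds <- function(labels, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# z-score new data with statistics estimated on the training rows only
.zscore_train_test <- function(X, train) {
  mu <- colMeans(X[train, , drop = FALSE])
  sd <- apply(X[train, , drop = FALSE], 2, stats::sd)
  sd[sd == 0 | is.na(sd)] <- 1
  list(train = scale(X[train, , drop = FALSE], mu, sd),
       test = scale(X[!train, , drop = FALSE], mu, sd))
}

.as_feature_matrix <- function(features) {
  stopifnot(is.data.frame(features) || is.matrix(features))
  X <- as.matrix(as.data.frame(features))
  storage.mode(X) <- "double"
  if (any(is.na(X))) stop("features contain missing values", call. = FALSE)
  X
}

.classification_result <- function(method, scores, labels, folds, extra = list(),
                                   B = 1000L, seed = 1L) {
  auc <- roc_auc(scores, labels)
  ci <- auc_bootstrap_ci(scores, labels, B = B,
                         seed = substream_seed(seed, "auc_ci"))
  structure(c(list(method = method, auc = auc, ci = ci, scores = scores,
                   labels = labels, fold = folds, n_folds = max(folds),
                   seed = seed), extra),
            class = "classification_result")
}

#' k-nearest-neighbour classification with cross-validated AUC
#'
#' Stratified five-fold cross-validation of a kNN classifier on a feature
#' table. Features are z-scored with training-fold statistics only;
#' distances are Euclidean. Each held-out record's score is the fraction of
#' its `k` nearest training neighbours carrying label 1; the ROC AUC is
#' computed on the pooled out-of-fold scores, with a percentile bootstrap
#' 95% confidence interval over the pooled (score, label) pairs.
#'
#' @param features Data frame or matrix of numeric features (the package's
#'   canonical table has the five motif counts, see
#'   [make_feature_dataset()]).
#' @param labels Binary 0/1 labels (1 = positive class).
#' @param k Number of neighbours (default 5).
#' @param n_folds Number of CV folds (default 5).
#' @param B Bootstrap replicates for the AUC interval.
#' @param seed Seed controlling fold assignment and the bootstrap.
#' @return A `classification_result` with fields `method`, `auc`, `ci`,
#'   `scores`, `labels`, `fold`, `k`; see [tidy.classification_result()].
#' @export
knn_cv <- function(features, labels, k = 5L, n_folds = 5L, B = 1000L, seed = 1L) {
  X <- .as_feature_matrix(features)
  labels <- .check_binary(labels)
  if (min(table(labels)) < 10L) stop("need at least 10 records per class", call. = FALSE)
  fold <- .stratified_folds(labels, n_folds, substream_seed(seed, "folds"))
  min_class <- min(table(labels[fold != 1L]))
  if (k >= min_class) stop("k is too large for the training-fold class sizes", call. = FALSE)
  scores <- numeric(length(labels))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    z <- .zscore_train_test(X, tr)
    pred <- class::knn(z$train, z$test, factor(labels[tr], levels = c(0, 1)),
                       k = k, prob = TRUE, use.all = TRUE)
    p <- attr(pred, "prob")
    scores[!tr] <- ifelse(pred == "1", p, 1 - p)
  }
  .classification_result("knn", scores, labels, fold,
                         extra = list(k = k), B = B, seed = seed)
}

#' PLS discriminant analysis with cross-validated AUC and importances
#'
#' Stratified five-fold cross-validation of a PLS-DA classifier: labels are
#' encoded ±1 and a PLS regression (via \pkg{mixOmics}) is fitted on
#' training folds, features z-scored with training-fold statistics. Held-out
#' records are scored by the continuous PLS prediction; AUC and its
#' bootstrap interval are computed on the pooled out-of-fold scores. The
#' signed variable importances are the PLS regression coefficients on the
#' standardized features, averaged across folds with signs preserved;
#' unsigned VIP scores are reported alongside.
#'
#' @inheritParams knn_cv
#' @param n_components Number of PLS components (default 2, at most the
#'   number of features).
#' @return A `classification_result` with additional fields `importances`
#'   (signed, named by feature) and `vip` (unsigned).
#' @export
plsda_cv <- function(features, labels, n_components = 2L, n_folds = 5L,
                     B = 1000L, seed = 1L) {
  X <- .as_feature_matrix(features)
  labels <- .check_binary(labels)
  if (min(table(labels)) < 10L) stop("need at least 10 records per class", call. = FALSE)
  if (n_components > ncol(X)) stop("n_components exceeds the number of features", call. = FALSE)
  fold <- .stratified_folds(labels, n_folds, substream_seed(seed, "folds"))
  scores <- numeric(length(labels))
  coefs <- matrix(0, nrow = ncol(X), ncol = n_folds,
                  dimnames = list(colnames(X), NULL))
  vips <- matrix(0, nrow = ncol(X), ncol = n_folds,
                 dimnames = list(colnames(X), NULL))
  y <- ifelse(labels == 1L, 1, -1)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    z <- .zscore_train_test(X, tr)
    fit <- mixOmics::pls(z$train, y[tr], ncomp = n_components,
                         mode = "regression", scale = FALSE)
    pr <- stats::predict(fit, z$test)
    scores[!tr] <- pr$predict[, 1, n_components]
    coefs[, f] <- pr$B.hat[, 1, n_components]
    vips[, f] <- mixOmics::vip(fit)[, n_components]
  }
  .classification_result("plsda", scores, labels, fold,
                         extra = list(n_components = n_components,
                                      importances = rowMeans(coefs),
                                      vip = rowMeans(vips)),
                         B = B, seed = seed)
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s: AUC %.3f  95%% CI [%.3f, %.3f]  (%d-fold CV, n = %d)\n",
              x$method, x$auc, x$ci[1], x$ci[2], x$n_folds, length(x$labels)))
  if (!is.null(x$importances)) {
    cat("signed importances:\n")
    print(round(x$importances, 3))
  }
  invisible(x)
}

#' Tidy a classification result
#'
#' @param x A `classification_result`.
#' @param ... Unused.
#' @return For PLS-DA, one row per feature with signed importance and VIP;
#'   for kNN, the per-record out-of-fold scores.
#' @export
tidy.classification_result <- function(x, ...) {
  if (!is.null(x$importances)) {
    tibble::tibble(feature = names(x$importances),
                   importance = unname(x$importances),
                   vip = unname(x$vip))
  } else {
    tibble::tibble(record = seq_along(x$scores), score = x$scores,
                   label = x$labels, fold = x$fold)
  }
}

#' @export
glance.classification_result <- function(x, ...) {
  tibble::tibble(method = x$method, auc = x$auc, ci_lo = x$ci[1],
                 ci_hi = x$ci[2], n = length(x$labels), n_folds = x$n_folds)
}

#' @export
autoplot.classification_result <- function(object, ...) {
  ord <- order(object$scores, decreasing = TRUE)
  lab <- object$labels[ord]
  df <- tibble::tibble(
    fpr = c(0, cumsum(lab == 0) / sum(lab == 0)),
    tpr = c(0, cumsum(lab == 1) / sum(lab == 1))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("%s ROC, AUC = %.3f", object$method, object$auc)) +
    ggplot2::theme_minimal()
}

#' Bar plot of signed PLS-DA variable importances
#'
#' @param result A `classification_result` from [plsda_cv()].
#' @return A ggplot object.
#' @export
plot_importances <- function(result) {
  stopifnot(inherits(result, "classification_result"),
            !is.null(result$importances))
  df <- tidy.classification_result(result)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$feature, abs(.data$importance)),
                                   y = .data$importance)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "signed importance (standardized PLS coefficient)") +
    ggplot2::theme_minimal()
}
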