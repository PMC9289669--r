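#' Nested cross-validation configuration
#'
#' @param k_outer outer stratified folds (default 10; the outer CV estimates
#'   generalization performance).
#' @param k_inner inner folds used for hyperparameter tuning (default 10).
#' @param mask_p uncorrected two-sample t-test threshold for the stage-1
#'   feature mask (default 0.05).
#' @param lasso_grid LASSO penalty (lambda) candidates for the stage-2
#'   L1-logistic selector.
#' @param svm_c_grid linear-SVM cost candidates.
#' @param n_permutations label permutations for [permutation_test]
#'   (default 1000).
#' @param seed integer seed driving fold assignment and permutations.
#' @param positive_level label treated as the positive class (sensitivity);
#'   default `"post_rt_re_pos"` when present, else the second factor level.
#' @return list of class `cv_config`.
#' @export
cv_config <- function(k_outer = 10, k_inner = 10, mask_p = 0.05,
                      lasso_grid = c(0.01, 0.05, 0.1, 0.2),
                      svm_c_grid = c(0.1, 1, 10),
                      n_permutations = 1000, seed = 1L,
                      positive_level = NULL) {
  stopifnot(k_outer >= 2, k_inner >= 2, mask_p > 0, mask_p <= 1,
            all(lasso_grid >= 0), all(svm_c_grid > 0))
  structure(list(k_outer = as.integer(k_outer), k_inner = as.integer(k_inner),
                 mask_p = mask_p, lasso_grid = sort(lasso_grid),
                 svm_c_grid = sort(svm_c_grid),
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), positive_level = positive_level),
            class = "cv_config")
}

#' Vectorize in-mask voxels into a subjects x voxels feature table
#'
#' Column j corresponds to the j-th in-mask voxel in column-major array
#' order (`which(mask)`); the mapping is stored in
#' `attr(, "voxel_index")` and is invertible via [features_to_map].
#'
#' @param maps list of `scalar_map`s on a shared grid.
#' @param mask logical array (e.g. the cohort intersection mask).
#' @return numeric matrix (subjects x voxels) with attributes
#'   `voxel_index` and `dim3` (the grid shape).
#' @export
extract_features <- function(maps, mask) {
  grid <- maps[[1]]$grid
  stopifnot(all(dim(mask) == grid$shape))
  idx <- which(mask)
  X <- t(vapply(maps, function(m) {
    v <- m$values[idx]
    if (any(!is.finite(v))) stop("extract_features: non-finite value in mask")
    v
  }, numeric(length(idx))))
  attr(X, "voxel_index") <- idx
  attr(X, "dim3") <- grid$shape
  X
}

#' Back-project a feature row to a 3D map
#'
#' @param row numeric vector of length `ncol(features)`.
#' @param features matrix from [extract_features] (for the voxel mapping).
#' @param grid the cohort `image_grid`.
#' @param kind `scalar_map` kind for the result.
#' @return a `scalar_map` with `row` at the in-mask voxels and 0 elsewhere.
#' @export
features_to_map <- function(row, features, grid, kind = "generic") {
  idx <- attr(features, "voxel_index")
  stopifnot(length(row) == length(idx))
  vals <- array(0, dim = grid$shape)
  vals[idx] <- row
  scalar_map(vals, grid, kind = kind)
}

# stratified fold assignment; errors if any fold would miss a class
stratified_folds <- function(y, k, rng_permute = sample) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    if (length(idx) < 2)
      stop(sprintf(
        "degenerate stratification: class '%s' has %d subject(s)",
        lv, length(idx)))
    fold[idx] <- 1L + (seq_along(idx) - 1L) %% k
    fold[idx] <- fold[idx][rng_permute(length(idx))]
  }
  fold
}

# vectorized pooled-variance two-sample t-test p-values per column
column_ttest_p <- function(X, y, positive) {
  a <- X[y == positive, , drop = FALSE]
  b <- X[y != positive, , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  if (na < 2 || nb < 2) stop("fold error: fewer than 2 subjects in a class")
  ma <- colMeans(a); mb <- colMeans(b)
  va <- colSums(sweep(a, 2, ma)^2); vb <- colSums(sweep(b, 2, mb)^2)
  sp2 <- (va + vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tt <- ifelse(se > 0, (ma - mb) / se, 0)
  2 * stats::pt(-abs(tt), na + nb - 2)
}

#' Fold-internal feature selection: t-test mask then LASSO
#'
#' Stage 1 keeps columns whose two-sample t-test p-value (uncorrected, the
#' training subjects only) is below `config$mask_p`. Stage 2 fits an
#' L1-penalized logistic model on the surviving columns and keeps the
#' nonzero-coefficient support. If the selection comes back empty, the
#' single smallest-p column is kept so every fold can fit a model.
#'
#' @param x training feature matrix.
#' @param y training labels (factor, 2 levels).
#' @param config a [cv_config].
#' @param lambda LASSO penalty; `NULL` picks from `config$lasso_grid` by
#'   inner-CV misclassification (ties toward the stronger penalty).
#' @return list: `cols` (selected column indices), `p` (stage-1 p-values),
#'   `stage1_cols`, `lambda`.
#' @export
fold_feature_select <- function(x, y, config = cv_config(), lambda = NULL) {
  y <- droplevels(as.factor(y))
  stopifnot(nlevels(y) == 2)
  pos <- positive_class(y, config)
  p <- column_ttest_p(x, y, pos)
  stage1 <- which(p < config$mask_p)
  if (is.null(lambda)) {
    lambda <- if (length(config$lasso_grid) == 1L) config$lasso_grid else {
      xs <- x[, stage1, drop = FALSE]
      if (ncol(xs) < 2) config$lasso_grid[length(config$lasso_grid)] else {
        cvfit <- glmnet::cv.glmnet(xs, y, family = "binomial",
                                   lambda = rev(config$lasso_grid),
                                   type.measure = "class",
                                   nfolds = min(config$k_inner, floor(length(y) / 2)))
        cvfit$lambda.1se
      }
    }
  }
  cols <- stage1
  if (length(stage1) >= 2 && lambda > 0) {
    fit <- suppressWarnings(
      glmnet::glmnet(x[, stage1, drop = FALSE], y, family = "binomial",
                     lambda = lambda, standardize = TRUE))
    beta <- as.numeric(fit$beta)
    cols <- stage1[beta != 0]
  }
  if (length(cols) == 0) cols <- which.min(p)
  list(cols = cols, p = p, stage1_cols = stage1, lambda = lambda)
}

positive_class <- function(y, config) {
  if (!is.null(config$positive_level) && config$positive_level %in% levels(y))
    return(config$positive_level)
  if ("post_rt_re_pos" %in% levels(y)) return("post_rt_re_pos")
  levels(y)[2]
}

# linear SVM fit on selected, standardized columns; returns predictor state
fit_linear_svm <- function(x, y, cols, cost, pos) {
  xs <- x[, cols, drop = FALSE]
  mu <- colMeans(xs)
  sdv <- apply(xs, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- sweep(sweep(xs, 2, mu), 2, sdv, "/")
  fit <- e1071::svm(xs, y, kernel = "linear", cost = cost, scale = FALSE,
                    probability = FALSE)
  w <- as.numeric(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # orient the decision value so larger => positive class
  flip <- fit$levels[1] != pos
  if (flip) { w <- -w; b <- -b }
  list(fit = fit, cols = cols, mu = mu, sd = sdv, w = w, b = b, pos = pos,
       flip = flip)
}

predict_linear_svm <- function(model, x) {
  xs <- sweep(sweep(x[, model$cols, drop = FALSE], 2, model$mu), 2,
              model$sd, "/")
  dv <- as.numeric(xs %*% model$w + model$b)
  cls <- ifelse(dv > 0, model$pos, setdiff(model$fit$levels, model$pos))
  list(decision = dv, class = cls)
}

pooled_metrics <- function(truth, pred, decision, pos) {
  neg <- setdiff(unique(as.character(truth)), pos)
  tp <- sum(truth == pos & pred == pos); fn <- sum(truth == pos & pred != pos)
  tn <- sum(truth != pos & pred != pos); fp <- sum(truth != pos & pred == pos)
  auc <- mann_whitney_auc(decision[truth == pos], decision[truth != pos])
  list(accuracy = (tp + tn) / length(truth),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       auc = auc,
       confusion = matrix(c(tp, fp, fn, tn), 2, 2,
                          dimnames = list(truth = c(pos, neg[1]),
                                          predicted = c(pos, neg[1]))))
}

# AUC as the normalized Mann-Whitney U of decision values
mann_whitney_auc <- function(dpos, dneg) {
  if (!length(dpos) || !length(dneg)) return(NA_real_)
  r <- rank(c(dpos, dneg), ties.method = "average")
  (sum(r[seq_along(dpos)]) - length(dpos) * (length(dpos) + 1) / 2) /
    (length(dpos) * length(dneg))
}

#' Nested stratified cross-validated linear SVM
#'
#' Outer stratified k-fold CV estimates performance; within each outer
#' training set an inner stratified CV jointly tunes the LASSO penalty and
#' SVM cost by mean inner-fold accuracy (ties broken toward the larger
#' penalty, then the smaller cost). Feature selection (t-test mask + LASSO)
#' is refit inside every training set and never sees the held-out subjects.
#' Predictions are pooled over outer test folds into accuracy, sensitivity
#' (positive class = RE-positive), specificity, and AUC (Mann-Whitney on
#' the decision values). When both hyperparameter grids are singletons the
#' inner loop is skipped.
#'
#' @param features subjects x voxels matrix (see [extract_features]).
#' @param labels 2-level factor (or coercible), aligned with the rows.
#' @param config a [cv_config].
#' @return object of class `classifier_report`: `folds` (per-outer-fold
#'   selections, hyperparameters, weights, test predictions and decision
#'   values, training-subject indices), `metrics` (pooled), `train_metrics`
#'   (refit-on-training pooled), `inner_accuracy`, `pooled` (per-subject
#'   predictions), `config`, `positive`.
#' @export
nested_cv <- function(features, labels, config = cv_config()) {
  y <- droplevels(as.factor(labels))
  stopifnot(nlevels(y) == 2, nrow(features) == length(y))
  pos <- positive_class(y, config)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  outer_fold <- stratified_folds(y, config$k_outer)
  grid <- expand.grid(lambda = config$lasso_grid, cost = config$svm_c_grid)
  # tie-break order: stronger regularization first
  grid <- grid[order(-grid$lambda, grid$cost), , drop = FALSE]
  folds <- vector("list", config$k_outer)
  pooled_pred <- character(length(y))
  pooled_dec <- numeric(length(y))
  train_pred <- list(); train_truth <- list(); train_dec <- list()
  inner_acc <- numeric(config$k_outer)
  for (f in seq_len(config$k_outer)) {
    te <- which(outer_fold == f)
    tr <- which(outer_fold != f)
    x_tr <- features[tr, , drop = FALSE]; y_tr <- y[tr]
    if (nlevels(droplevels(y_tr)) < 2)
      stop("degenerate stratification: single-class outer training fold")
    kin <- min(config$k_inner, min(table(droplevels(y_tr))))
    if (nrow(grid) > 1L && kin >= 2L) {
      inner_fold <- stratified_folds(y_tr, kin)
      acc <- matrix(NA_real_, nrow(grid), kin)
      for (g in seq_len(nrow(grid))) {
        for (i in seq_len(kin)) {
          vi <- which(inner_fold == i); ti <- which(inner_fold != i)
          sel <- fold_feature_select(x_tr[ti, , drop = FALSE], y_tr[ti],
                                     config, lambda = grid$lambda[g])
          mdl <- fit_linear_svm(x_tr[ti, , drop = FALSE], y_tr[ti],
                                sel$cols, grid$cost[g], pos)
          pr <- predict_linear_svm(mdl, x_tr[vi, , drop = FALSE])
          acc[g, i] <- mean(pr$class == as.character(y_tr[vi]))
        }
      }
      macc <- rowMeans(acc)
      best <- which.max(macc)   # first max respects the tie-break ordering
      lambda_f <- grid$lambda[best]; cost_f <- grid$cost[best]
      inner_acc[f] <- macc[best]
    } else {
      lambda_f <- grid$lambda[1]; cost_f <- grid$cost[1]
      inner_acc[f] <- NA_real_
    }
    sel <- fold_feature_select(x_tr, y_tr, config, lambda = lambda_f)
    mdl <- fit_linear_svm(x_tr, y_tr, sel$cols, cost_f, pos)
    pr <- predict_linear_svm(mdl, features[te, , drop = FALSE])
    pooled_pred[te] <- pr$class
    pooled_dec[te] <- pr$decision
    pr_tr <- predict_linear_svm(mdl, x_tr)
    train_pred[[f]] <- pr_tr$class
    train_truth[[f]] <- as.character(y_tr)
    train_dec[[f]] <- pr_tr$decision
    folds[[f]] <- list(test_idx = te, train_idx = tr,
                       selection_input_idx = tr,
                       selected_cols = sel$cols,
                       stage1_cols = sel$stage1_cols,
                       lambda = lambda_f, cost = cost_f,
                       weights = mdl$w,
                       test_decision = pr$decision, test_pred = pr$class)
  }
  metrics <- pooled_metrics(as.character(y), pooled_pred, pooled_dec, pos)
  tm <- pooled_metrics(unlist(train_truth), unlist(train_pred),
                       unlist(train_dec), pos)
  structure(list(folds = folds, metrics = metrics, train_metrics = tm,
                 inner_accuracy = inner_acc,
                 pooled = data.frame(truth = as.character(y),
                                     predicted = pooled_pred,
                                     decision = pooled_dec,
                                     fold = outer_fold),
                 config = config, positive = pos,
                 n_features = ncol(features)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("classifier_report: %d-fold nested CV, %d subjects, %d features\n",
              x$config$k_outer, nrow(x$pooled), x$n_features))
  cat(sprintf("  pooled test: accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f\n",
              m$accuracy, m$sensitivity, m$specificity, m$auc))
  if (!is.null(x$permutation_p))
    cat(sprintf("  permutation p = %.4g (%d permutations)\n",
                x$permutation_p, length(x$permutation_null)))
  invisible(x)
}

#' @export
summary.classifier_report <- function(object, ...) {
  print(object)
  cat(sprintf("  train (refit) : accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f\n",
              object$train_metrics$accuracy, object$train_metrics$sensitivity,
              object$train_metrics$specificity, object$train_metrics$auc))
  sel <- lengths(lapply(object$folds, `[[`, "selected_cols"))
  cat(sprintf("  selected features per fold: %s\n",
              paste(sel, collapse = ", ")))
  invisible(object)
}

#' Permutation test of classifier performance
#'
#' Repeatedly permutes the labels, reruns the full nested CV, and records
#' the pooled accuracy; `p = (1 + #null >= observed) / (n_permutations + 1)`
#' (the add-one convention, so p is never 0).
#'
#' @param features,labels as in [nested_cv].
#' @param config a [cv_config] (`n_permutations` >= 100).
#' @param observed_metric observed pooled accuracy; computed via
#'   [nested_cv] when `NULL`.
#' @return list: `p`, `null` (permutation accuracies), `observed`.
#' @export
permutation_test <- function(features, labels, config = cv_config(),
                             observed_metric = NULL) {
  stopifnot(config$n_permutations >= 100)
  if (is.null(observed_metric))
    observed_metric <- nested_cv(features, labels, config)$metrics$accuracy
  y <- droplevels(as.factor(labels))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  null <- numeric(config$n_permutations)
  for (b in seq_len(config$n_permutations)) {
    set.seed(config$seed + 1000L + b)
    yb <- y[sample.int(length(y))]
    cfg_b <- config
    cfg_b$seed <- config$seed + 2000L + b
    null[b] <- nested_cv(features, yb, cfg_b)$metrics$accuracy
  }
  list(p = (1 + sum(null >= observed_metric)) / (config$n_permutations + 1),
       null = null, observed = observed_metric)
}

#' Back-project SVM weights to voxel space
#'
#' Per voxel: the mean absolute SVM weight over the outer folds in which the
#' voxel was selected (0 where never selected), plus the selection
#' frequency (fraction of folds).
#'
#' @param report a `classifier_report`.
#' @param features the feature matrix used (for the voxel mapping).
#' @param grid the cohort `image_grid`.
#' @return list: `weight_map` (`scalar_map`, kind `"weight"`),
#'   `selection_frequency` (`scalar_map`).
#' @export
weight_backprojection <- function(report, features, grid) {
  p <- ncol(features)
  wsum <- numeric(p); nsel <- numeric(p)
  for (f in report$folds) {
    wsum[f$selected_cols] <- wsum[f$selected_cols] + abs(f$weights)
    nsel[f$selected_cols] <- nsel[f$selected_cols] + 1
  }
  wmean <- ifelse(nsel > 0, wsum / nsel, 0)
  list(weight_map = features_to_map(wmean, features, grid, kind = "weight"),
       selection_frequency = features_to_map(nsel / length(report$folds),
                                             features, grid))
}

#' Structural leakage audit of a nested-CV report
#'
#' Verifies, for every outer fold, that (a) the subjects whose data entered
#' feature selection are disjoint from the test subjects, (b) every subject
#' appears in exactly one outer test fold, and (c) the stored selection is
#' reproducible from the training subjects alone (stage-1 mask and LASSO
#' support recomputed from `features[train_idx, ]` match the stored
#' columns).
#'
#' @param report a `classifier_report`.
#' @param features,labels the data the report was computed from.
#' @return `TRUE` (invisibly) if the audit passes; otherwise stops with the
#'   offending fold.
#' @export
audit_leakage <- function(report, features, labels) {
  y <- droplevels(as.factor(labels))
  seen <- integer(0)
  for (f in seq_along(report$folds)) {
    fd <- report$folds[[f]]
    if (length(intersect(fd$selection_input_idx, fd$test_idx)) > 0)
      stop(sprintf("leakage: fold %d selection inputs include test subjects", f))
    if (!setequal(union(fd$train_idx, fd$test_idx), seq_len(nrow(features))))
      stop(sprintf("fold %d does not partition the cohort", f))
    seen <- c(seen, fd$test_idx)
    sel <- fold_feature_select(features[fd$train_idx, , drop = FALSE],
                               y[fd$train_idx], report$config,
                               lambda = fd$lambda)
    if (!identical(sort(sel$cols), sort(fd$selected_cols)))
      stop(sprintf("fold %d selection not reproducible from training data", f))
  }
  if (anyDuplicated(seen) || length(seen) != nrow(features))
    stop("subjects do not appear in exactly one outer test fold")
  invisible(TRUE)
}
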