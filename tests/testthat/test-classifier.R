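planted_features <- function(n = 40, p = 60, shift = 2, planted = 5,
                             seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  y <- factor(rep(c("neg", "pos"), each = n / 2), levels = c("neg", "pos"))
  X[y == "pos", planted] <- X[y == "pos", planted] + shift
  list(X = X, y = y, planted = planted)
}

fast_cfg <- function(...) cv_config(k_outer = 5, k_inner = 3,
                                    lasso_grid = 0.1, svm_c_grid = 1,
                                    positive_level = "pos", ...)

test_that("feature extraction is shaped correctly and invertible", {
  set.seed(31)
  g <- image_grid(c(6, 6, 6))
  mask <- array(FALSE, dim = g$shape); mask[which(g$mask)[1:100]] <- TRUE
  maps <- lapply(1:40, function(s)
    scalar_map(array(rnorm(216), dim = g$shape) * mask, g, "coupling_z",
               meta = list(mask = mask)))
  X <- extract_features(maps, mask)
  expect_equal(dim(X), c(40, 100))
  # back-projection reproduces the subject's in-mask map exactly
  bp <- features_to_map(X[7, ], X, g)
  expect_equal(bp$values[mask], maps[[7]]$values[mask])
  expect_true(all(bp$values[!mask] == 0))
  # column <-> voxel mapping round-trips
  idx <- attr(X, "voxel_index")
  for (j in sample(100, 5))
    expect_equal(X[3, j], maps[[3]]$values[idx[j]])
  # NaN inside the mask is a validation error
  bad <- maps
  bad[[1]]$values[idx[5]] <- NaN
  expect_error(extract_features(bad, mask), "non-finite")
})

test_that("fold selection finds a planted column and honours disabled filters", {
  for (seed in 1:10) {
    pf <- planted_features(shift = 3, planted = 5, seed = seed)
    sel <- fold_feature_select(pf$X, pf$y, fast_cfg(), lambda = 0.1)
    expect_true(5 %in% sel$cols)
  }
  # null labels select far fewer columns than a planted signal does
  set.seed(32)
  sizes_null <- sizes_sig <- numeric(10)
  for (r in 1:10) {
    pf <- planted_features(shift = 2.5, planted = 1:5, seed = 100 + r)
    sizes_sig[r] <- length(fold_feature_select(pf$X, pf$y, fast_cfg(),
                                               lambda = 0.05)$cols)
    ynull <- pf$y[sample.int(length(pf$y))]
    sizes_null[r] <- length(fold_feature_select(pf$X, ynull, fast_cfg(),
                                                lambda = 0.05)$cols)
  }
  expect_lt(mean(sizes_null), mean(sizes_sig))
  # mask_p = 1 and zero penalty: every column survives stage 1
  pf <- planted_features(seed = 1)
  sel_all <- fold_feature_select(pf$X, pf$y, cv_config(mask_p = 1,
                                                       lasso_grid = 0),
                                 lambda = 0)
  expect_equal(sel_all$stage1_cols, seq_len(ncol(pf$X)))
  expect_equal(sel_all$cols, seq_len(ncol(pf$X)))
})

test_that("nested CV is deterministic and internally consistent", {
  pf <- planted_features(shift = 1.5, seed = 33)
  cfg <- cv_config(k_outer = 5, k_inner = 3, lasso_grid = c(0.05, 0.1),
                   svm_c_grid = c(0.5, 1), positive_level = "pos", seed = 5)
  r1 <- nested_cv(pf$X, pf$y, cfg)
  r2 <- nested_cv(pf$X, pf$y, cfg)
  expect_identical(r1$pooled, r2$pooled)
  expect_identical(r1$metrics, r2$metrics)
  # pooled metrics recompute from the pooled confusion matrix
  cm <- r1$metrics$confusion
  expect_equal(r1$metrics$accuracy, sum(diag(cm)) / sum(cm))
  expect_equal(r1$metrics$sensitivity, cm[1, 1] / sum(cm[1, ]))
  expect_equal(r1$metrics$specificity, cm[2, 2] / sum(cm[2, ]))
  # every subject appears in exactly one outer test fold
  expect_setequal(unlist(lapply(r1$folds, `[[`, "test_idx")),
                  seq_len(nrow(pf$X)))
  expect_equal(sum(lengths(lapply(r1$folds, `[[`, "test_idx"))), nrow(pf$X))
  # metrics live in [0, 1]
  for (m in c("accuracy", "sensitivity", "specificity", "auc"))
    expect_true(r1$metrics[[m]] >= 0 && r1$metrics[[m]] <= 1)
})

test_that("AUC from decision values equals the Mann-Whitney statistic (pROC oracle)", {
  skip_if_not_installed("pROC")
  pf <- planted_features(shift = 1, seed = 34)
  r <- nested_cv(pf$X, pf$y, fast_cfg(seed = 6))
  auc_oracle <- as.numeric(pROC::auc(pROC::roc(
    response = r$pooled$truth, predictor = r$pooled$decision,
    levels = c("neg", "pos"), direction = "<", quiet = TRUE)))
  expect_equal(r$metrics$auc, auc_oracle, tolerance = 1e-12)
  w <- wilcox.test(r$pooled$decision[r$pooled$truth == "pos"],
                   r$pooled$decision[r$pooled$truth == "neg"],
                   exact = FALSE)
  expect_equal(r$metrics$auc,
               unname(w$statistic) / (sum(pf$y == "pos") * sum(pf$y == "neg")))
})

test_that("permutation test follows the add-one convention at the extremes", {
  pf <- planted_features(shift = 0, seed = 35)
  cfg <- fast_cfg(n_permutations = 100, seed = 7)
  pt <- permutation_test(pf$X, pf$y, cfg, observed_metric = 1.01)
  expect_equal(pt$p, 1 / 101)          # observed beats every permutation
  pt2 <- permutation_test(pf$X, pf$y, cfg, observed_metric = -1)
  expect_equal(pt2$p, 1)               # observed below every permutation
  expect_equal(length(pt$null), 100)
  expect_identical(pt$null, pt2$null)  # same seed, same null draws
})

test_that("weight back-projection takes mean absolute weights and selection frequency", {
  g <- image_grid(c(4, 4, 4))
  X <- matrix(rnorm(10 * 6), 10, 6)
  attr(X, "voxel_index") <- which(g$mask)[1:6]
  report <- list(folds = list(
    list(selected_cols = c(1, 3), weights = c(2, -2)),
    list(selected_cols = c(3), weights = c(4))))
  wb <- weight_backprojection(report, X, g)
  idx <- attr(X, "voxel_index")
  expect_equal(wb$weight_map$values[idx[1]], 2)   # |2| over one fold
  expect_equal(wb$weight_map$values[idx[3]], 3)   # mean(|-2|, |4|)
  expect_equal(wb$weight_map$values[idx[2]], 0)   # never selected
  expect_equal(wb$selection_frequency$values[idx[1]], 0.5)
  expect_equal(wb$selection_frequency$values[idx[2]], 0)
})

test_that("the leakage audit passes honest reports and catches tampered ones", {
  pf <- planted_features(shift = 1, seed = 36)
  r <- nested_cv(pf$X, pf$y, fast_cfg(seed = 8))
  expect_true(audit_leakage(r, pf$X, pf$y))
  bad <- r
  bad$folds[[1]]$selection_input_idx <- c(bad$folds[[1]]$selection_input_idx,
                                          bad$folds[[1]]$test_idx[1])
  expect_error(audit_leakage(bad, pf$X, pf$y), "selection inputs include test")
  bad2 <- r
  bad2$folds[[2]]$selected_cols <- c(bad2$folds[[2]]$selected_cols, 999L)
  expect_error(audit_leakage(bad2, pf$X, pf$y), "not reproducible")
})

test_that("degenerate stratification is an explicit error", {
  X <- matrix(rnorm(10 * 4), 10, 4)
  y <- factor(c(rep("a", 9), "b"))
  expect_error(nested_cv(X, y, fast_cfg()), "degenerate stratification")
})
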