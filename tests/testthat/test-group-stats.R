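# build per-subject single- or few-voxel coupling_z maps from a matrix of
# values (rows = subjects)
maps_from_matrix <- function(vals, g) {
  lapply(seq_len(nrow(vals)), function(s) {
    a <- array(0, dim = g$shape)
    a[seq_len(ncol(vals))] <- vals[s, ]
    mask <- array(FALSE, dim = g$shape); mask[seq_len(ncol(vals))] <- TRUE
    scalar_map(a, g, "coupling_z", meta = list(mask = mask))
  })
}

rand_subjects <- function(n, groups) {
  data.frame(subject_id = sprintf("s%02d", seq_len(n)), group = groups,
             age_years = runif(n, 30, 60),
             sex = sample(c("male", "female"), n, replace = TRUE))
}

test_that("voxelwise GLM matches lm() on extracted data to 1e-8", {
  set.seed(21)
  g <- image_grid(c(4, 4, 4))
  n <- 24
  subj <- rand_subjects(n, rep(c("a", "b"), each = 12))
  vals <- matrix(rnorm(n * 5), n, 5)
  vals[subj$group == "b", 2] <- vals[subj$group == "b", 2] + 1
  res <- glm_contrast(maps_from_matrix(vals, g), subj, "a", "b")
  for (v in 1:5) {
    df_ <- data.frame(y = vals[, v], grp = as.numeric(subj$group == "b"),
                      age = subj$age_years - mean(subj$age_years),
                      sex = as.numeric(subj$sex == "male"))
    fit <- summary(lm(y ~ grp + age + sex, data = df_))
    expect_equal(res$t_map$values[v], fit$coefficients["grp", "t value"],
                 tolerance = 1e-8)
    expect_equal(res$p_map$values[v], fit$coefficients["grp", "Pr(>|t|)"],
                 tolerance = 1e-8)
  }
  expect_equal(res$df, n - 4)
})

test_that("identical groups relabelled give t = 0 everywhere", {
  set.seed(22)
  g <- image_grid(c(4, 4, 4))
  vals_half <- matrix(rnorm(10 * 6), 10, 6)
  vals <- rbind(vals_half, vals_half)  # group b is a copy of group a
  subj <- data.frame(subject_id = sprintf("s%02d", 1:20),
                     group = rep(c("a", "b"), each = 10),
                     age_years = rep(runif(10, 30, 60), 2),
                     sex = rep(sample(c("male", "female"), 10, TRUE), 2))
  res <- glm_contrast(maps_from_matrix(vals, g), subj, "a", "b")
  expect_lt(max(abs(res$t_map$values[res$mask])), 1e-10)
  expect_gt(min(res$p_map$values[res$mask]), 1 - 1e-9)
})

test_that("a rank-deficient design fails naming the collinear column", {
  set.seed(23)
  g <- image_grid(c(3, 3, 3))
  subj <- rand_subjects(12, rep(c("a", "b"), each = 6))
  subj$sex <- "male"      # constant column, collinear with the intercept
  vals <- matrix(rnorm(12 * 3), 12, 3)
  expect_error(glm_contrast(maps_from_matrix(vals, g), subj, "a", "b"),
               "collinear.*sex")
})

test_that("without covariates the GLM reduces to the pooled-variance t-test", {
  set.seed(24)
  g <- image_grid(c(3, 3, 3))
  subj <- rand_subjects(20, rep(c("a", "b"), each = 10))
  vals <- matrix(rnorm(20 * 4), 20, 4)
  res <- glm_contrast(maps_from_matrix(vals, g), subj, "a", "b",
                      covariates = character(0))
  for (v in 1:4) {
    tt <- t.test(vals[subj$group == "b", v], vals[subj$group == "a", v],
                 var.equal = TRUE)
    expect_equal(res$t_map$values[v], unname(tt$statistic), tolerance = 1e-8)
    expect_equal(res$p_map$values[v], tt$p.value, tolerance = 1e-8)
  }
})

test_that("BH-FDR matches an independent step-up oracle", {
  # spec worked case: all four rejected at q = 0.05
  fd <- fdr_correct(c(0.01, 0.02, 0.03, 0.04), 0.05)
  expect_true(all(fd$significant))
  expect_equal(fd$p_threshold, 0.04)
  # all-ones: nothing rejected
  expect_equal(fdr_correct(rep(1, 10), 0.05)$n_rejected, 0)
  set.seed(25)
  for (r in 1:100) {
    m <- sample(5:200, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(fdr_correct(p, q)$significant, bh_oracle(p, q))
    # BH rejects at least everything Bonferroni rejects
    expect_true(all(fdr_correct(p, q)$significant[p <= q / m]))
  }
})

test_that("smoothness estimation recovers known FWHM and degenerates sanely", {
  set.seed(26)
  g <- image_grid(c(20, 22, 20), c(3, 3, 3))
  mk <- function(fwhm) lapply(1:8, function(i)
    smooth_map(scalar_map(array(rnorm(prod(g$shape)), dim = g$shape), g),
               fwhm, masked = FALSE))
  est6 <- estimate_smoothness(mk(6))
  expect_true(all(est6 > 5 & est6 < 7))
  est0 <- estimate_smoothness(lapply(1:8, function(i)
    scalar_map(array(rnorm(prod(g$shape)), dim = g$shape), g)))
  expect_true(all(abs(est0 - 3) / 3 < 0.25))
  est3 <- estimate_smoothness(mk(3)); est12 <- estimate_smoothness(mk(12))
  expect_true(all(est3 < est6 & est6 < est12))
  cst <- lapply(1:2, function(i) scalar_map(array(1, dim = g$shape), g))
  expect_error(estimate_smoothness(cst), "constant residual")
  expect_error(estimate_smoothness(mk(6)[1]), "at least 2")
})

test_that("alphasim honours its anchor cases and is seed-reproducible", {
  g <- image_grid(c(12, 12, 12), c(3, 3, 3))
  a1 <- alphasim_threshold(g, 6, voxel_p = 0.001, cluster_alpha = 1.0,
                           n_iter = 100, seed = 9)
  expect_equal(a1$k_threshold_voxels, 1)
  a2 <- alphasim_threshold(g, 6, voxel_p = 0.01, cluster_alpha = 0.05,
                           n_iter = 150, seed = 9)
  a3 <- alphasim_threshold(g, 6, voxel_p = 0.01, cluster_alpha = 0.05,
                           n_iter = 150, seed = 9)
  expect_identical(a2$max_cluster_null, a3$max_cluster_null)
  # the threshold satisfies its defining inequality, and k - 1 violates it
  k <- a2$k_threshold_voxels
  expect_lte(mean(a2$max_cluster_null >= k), 0.05)
  if (k > 1) expect_gt(mean(a2$max_cluster_null >= k - 1), 0.05)
})

test_that("cluster correction recovers an injected cluster and keeps signs apart", {
  set.seed(27)
  g <- image_grid(c(12, 12, 12), c(3, 3, 3))
  n <- 20
  base <- matrix(rnorm(n * prod(g$shape), sd = 0.3), n, prod(g$shape))
  pos_block <- as.vector(sphere_block(g$shape, c(4, 4, 4), 2))
  neg_block <- as.vector(sphere_block(g$shape, c(9, 9, 9), 2))
  grp <- rep(c("a", "b"), each = 10)
  base[grp == "b", pos_block] <- base[grp == "b", pos_block] + 2
  base[grp == "b", neg_block] <- base[grp == "b", neg_block] - 2
  maps <- lapply(seq_len(n), function(s)
    scalar_map(array(base[s, ], dim = g$shape), g, "coupling_z",
               meta = list(mask = g$mask)))
  subj <- rand_subjects(n, grp)
  gl <- glm_contrast(maps, subj, "a", "b")
  fake_as <- structure(list(voxel_p = 0.001, k_threshold_voxels = 5,
                            connectivity = 26), class = "alphasim_result")
  rep_ <- apply_cluster_correction(gl, fake_as)
  expect_equal(nrow(rep_), 2)
  expect_setequal(rep_$sign, c("positive", "negative"))
  pk <- rep_[rep_$sign == "positive", ]
  pk_lin <- (pk$i + 1) + pk$j * g$shape[1] + pk$k * g$shape[1] * g$shape[2]
  expect_true(pk_lin %in% which(pos_block))
  # nothing survives when no voxel passes the voxel threshold
  null_maps <- lapply(seq_len(n), function(s)
    scalar_map(array(rnorm(prod(g$shape)), dim = g$shape), g, "coupling_z",
               meta = list(mask = g$mask)))
  gl0 <- glm_contrast(null_maps, subj, "a", "b")
  fake_as$voxel_p <- 1e-12
  expect_equal(nrow(apply_cluster_correction(gl0, fake_as)), 0)
})

test_that("dose correlation is exact on constructed data and matches cor.test", {
  set.seed(28)
  g <- image_grid(c(6, 6, 6))
  n <- 12
  dose <- rnorm(n, 66, 8)
  tmask <- array(FALSE, dim = g$shape); tmask[1:20] <- TRUE
  vals <- matrix(rnorm(n * 20), n, 20)
  vals[, 3] <- -0.1 * dose + 5          # exact linear relation at voxel 3
  maps <- lapply(seq_len(n), function(s) {
    a <- array(0, dim = g$shape); a[1:20] <- vals[s, ]
    scalar_map(a, g, "coupling_z", meta = list(mask = tmask))
  })
  subj <- data.frame(mdrt_left_gy = dose, mdrt_right_gy = dose)
  dc <- dose_correlation(maps, subj, "left", tmask, q = 0.05)
  expect_equal(dc$r_map$values[3], -1)
  expect_equal(dc$p_map$values[3], 0)
  expect_true(dc$significant[3])
  for (v in c(1, 5, 17)) {
    ct <- cor.test(dose, vals[, v])
    expect_equal(dc$r_map$values[v], unname(ct$estimate), tolerance = 1e-10)
    expect_equal(dc$p_map$values[v], ct$p.value, tolerance = 1e-10)
  }
  # guards
  expect_error(dose_correlation(maps, data.frame(mdrt_left_gy = rep(66, n),
                                                 mdrt_right_gy = dose),
                                "left", tmask), "zero dose variance")
  subj4 <- subj; subj4$mdrt_left_gy[5:12] <- NA
  expect_error(dose_correlation(maps, subj4, "left", tmask), "fewer than 5")
  # pairwise deletion drops only the missing-dose subjects
  subj5 <- subj; subj5$mdrt_left_gy[1:3] <- NA
  expect_equal(dose_correlation(maps, subj5, "left", tmask)$n_subjects, n - 3)
})

test_that("voxelwise GLM p-values are calibrated on a pure-noise contrast", {
  set.seed(29)
  g <- image_grid(c(8, 8, 8))
  rates <- vapply(1:10, function(r) {
    n <- 30
    vals <- matrix(rnorm(n * 300), n, 300)
    subj <- rand_subjects(n, rep(c("a", "b"), each = 15))
    res <- glm_contrast(maps_from_matrix(vals, g), subj, "a", "b")
    mean(res$p_map$values[res$mask] < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.05), 0.01)
})
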