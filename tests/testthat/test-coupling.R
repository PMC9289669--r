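make_map <- function(vals, g, kind = "generic", mask = NULL) {
  scalar_map(vals, g, kind, meta = if (is.null(mask)) list() else
    list(mask = mask))
}

test_that("coupling ratio divides ReHo by GM and applies the GM floor", {
  g <- image_grid(c(5, 5, 5))
  reho <- make_map(array(0.5, dim = c(5, 5, 5)), g, "reho")
  gmv <- array(0.25, dim = c(5, 5, 5))
  gmv[1, 1, 1] <- 0.05            # below the 0.1 floor
  gm <- make_map(gmv, g, "gm_volume")
  cp <- coupling_ratio(reho, gm)
  expect_equal(cp$values[2, 2, 2], 2.0)
  expect_false(cp$meta$mask[1, 1, 1])
  expect_equal(cp$values[1, 1, 1], 0)
  expect_equal(cp$meta$n_gm_excluded, 1)
  expect_true(all(is.finite(cp$values)))
  # mismatched grids are rejected
  g2 <- image_grid(c(5, 5, 5), c(2, 2, 2))
  expect_error(coupling_ratio(reho, make_map(gmv, g2, "gm_volume")),
               "grids differ")
})

test_that("z-scoring standardizes in-mask values; degenerate maps warn", {
  set.seed(1)
  g <- image_grid(c(6, 6, 6))
  cp <- make_map(array(runif(216, 0.5, 3), dim = c(6, 6, 6)), g, "coupling",
                 mask = g$mask)
  cz <- transform_coupling(cp)
  inm <- cz$values[g$mask]
  expect_equal(mean(inm), 0, tolerance = 1e-12)
  expect_equal(sd(inm), 1, tolerance = 1e-12)
  # worked case: in-mask mean 2, sd 0.5; the voxel at 2.5 maps to exactly 1
  vals5 <- c(2.5, 1.5, 2.5, 1.5, 2)
  stopifnot(mean(vals5) == 2, sd(vals5) == 0.5)
  v <- array(0, dim = c(6, 6, 6))
  mask2 <- array(FALSE, dim = c(6, 6, 6)); mask2[1:5] <- TRUE
  v[1:5] <- vals5
  czv <- transform_coupling(make_map(v, g, "coupling", mask = mask2))
  expect_equal(czv$values[1], 1.0)
  # constant map: all-zero with a warning
  cst <- make_map(array(0.5, dim = c(6, 6, 6)), g, "coupling", mask = g$mask)
  expect_warning(czc <- transform_coupling(cst), "zero in-mask variance")
  expect_true(all(czc$values == 0))
})

test_that("the atanh variant clips into the domain and logs the clip count", {
  g <- image_grid(c(4, 4, 4))
  v <- array(0, dim = c(4, 4, 4))
  v[1, 1, 1] <- 0.5; v[2, 1, 1] <- 1.7   # 1.7 is outside atanh's domain
  cp <- make_map(v, g, "coupling", mask = g$mask)
  cz <- transform_coupling(cp, coupling_params(transform = "atanh"))
  expect_equal(cz$values[3, 3, 3], 0)            # atanh(0) = 0
  expect_equal(cz$values[1, 1, 1], atanh(0.5))
  expect_equal(cz$values[2, 1, 1], atanh(1 - 1e-6))
  expect_equal(cz$meta$n_clipped, 1)
})

test_that("Gaussian smoothing matches the analytic separable kernel", {
  g <- image_grid(c(15, 15, 15), c(3, 3, 3))
  imp <- array(0, dim = c(15, 15, 15)); imp[8, 8, 8] <- 1
  sm <- smooth_map(scalar_map(imp, g), 6, masked = FALSE)
  sig <- 6 / (3 * 2 * sqrt(2 * log(2)))
  k1 <- dnorm((-7:7) / sig); k1 <- k1 / sum(k1)
  oracle <- outer(outer(k1, k1), k1)
  expect_lt(max(abs(sm$values - oracle)), 1e-6)
  # fwhm = 0 is the identity
  expect_identical(smooth_map(scalar_map(imp, g), 0)$values, imp)
})

test_that("unmasked smoothing preserves the map sum; masked smoothing fixes constants", {
  set.seed(4)
  g <- image_grid(c(10, 12, 10), c(3, 3, 3))
  m <- scalar_map(array(runif(1200), dim = c(10, 12, 10)), g)
  sm <- smooth_map(m, 7.5, masked = FALSE)
  expect_equal(sum(sm$values), sum(m$values), tolerance = 1e-9)
  mask <- array(FALSE, dim = c(10, 12, 10)); mask[3:8, 3:10, 3:8] <- TRUE
  gm <- image_grid(c(10, 12, 10), c(3, 3, 3), mask = mask)
  cst <- scalar_map(array(3.7, dim = c(10, 12, 10)), gm)
  smc <- smooth_map(cst, 6, masked = TRUE)
  expect_equal(max(abs(smc$values[mask] - 3.7)), 0, tolerance = 1e-12)
  expect_true(all(smc$values[!mask] == 0))
})

test_that("the subject pipeline is the composition of its stages and deterministic", {
  set.seed(5)
  shape <- c(10, 10, 10); nt <- 16
  g <- image_grid(shape)
  b <- bold_series(array(rnorm(prod(shape) * nt), dim = c(shape, nt)), g, 2.4)
  gm <- scalar_map(array(runif(prod(shape), 0.2, 0.9), dim = shape), g,
                   "gm_volume")
  prm <- coupling_params()
  direct <- subject_coupling_pipeline(b, gm)
  manual <- smooth_map(transform_coupling(coupling_ratio(reho_map(b), gm,
                                                         prm), prm),
                       prm$smooth_fwhm_mm)
  expect_equal(direct$values, manual$values)
  expect_equal(subject_coupling_pipeline(b, gm)$values, direct$values)
})

test_that("a uniform ratio map z-transforms to all zeros downstream", {
  g <- image_grid(c(6, 6, 6))
  reho <- make_map(array(0.3, dim = c(6, 6, 6)), g, "reho")
  gm <- make_map(array(0.6, dim = c(6, 6, 6)), g, "gm_volume")
  cp <- coupling_ratio(reho, gm)
  expect_true(all(abs(cp$values[cp$meta$mask] - 0.5) < 1e-12))
  expect_warning(cz <- transform_coupling(cp))
  expect_true(all(cz$values == 0))
})
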