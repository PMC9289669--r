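test_that("the generator is bit-reproducible from its seed", {
  cfg <- quick_cohort_config()
  a <- generate_cohort(cfg, seed = 3)
  b <- generate_cohort(cfg, seed = 3)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$bold[[1]]$data, b$bold[[1]]$data)
  expect_identical(a$gm[[7]]$values, b$gm[[7]]$values)
  expect_identical(a$truth, b$truth)
  c_ <- generate_cohort(cfg, seed = 4)
  expect_false(identical(a$bold[[1]]$data, c_$bold[[1]]$data))
})

test_that("the default configuration reproduces the study cohort structure", {
  dc <- default_cohort()
  subj <- dc$cohort$subjects
  expect_equal(nrow(subj), 62)
  expect_equal(as.integer(table(subj$group)[c("pre_rt", "post_rt_re_neg",
                                              "post_rt_re_pos")]),
               c(22L, 22L, 18L))
  # pre-RT subjects carry no dose or interval (recorded as NA)
  pre <- subj[subj$group == "pre_rt", ]
  expect_true(all(is.na(pre$mdrt_left_gy)) && all(is.na(pre$mdrt_right_gy)))
  expect_true(all(is.na(pre$rt_to_scan_months)))
  # dose missingness mirrors the clinical table: 3 RE-negative, 10 RE-positive
  expect_equal(sum(is.na(subj$mdrt_left_gy[subj$group == "post_rt_re_neg"])), 3)
  expect_equal(sum(is.na(subj$mdrt_left_gy[subj$group == "post_rt_re_pos"])), 10)
  # sex split per group matches the clinical counts
  expect_equal(as.integer(table(subj$sex[subj$group == "pre_rt"])[c("male", "female")]),
               c(18L, 4L))
  # recorded doses live on the prescribed Gy scale
  d <- c(subj$mdrt_left_gy, subj$mdrt_right_gy)
  expect_gt(mean(d, na.rm = TRUE), 55)
  expect_lt(mean(d, na.rm = TRUE), 77)
  # GM maps live in [0, 1]; BOLD has no NaN in the mask
  gmv <- dc$cohort$gm[[1]]$values
  expect_true(all(gmv >= 0 & gmv <= 1))
  # every effect cluster sits inside the analysis mask
  for (cl in dc$cohort$truth$effect_clusters)
    expect_true(all(dc$cohort$grid$mask[cl$voxels]))
})

test_that("an effect cluster outside the mask is rejected at config time", {
  cfg <- quick_cohort_config()
  cfg$effect_clusters[[1]]$center <- c(1, 1, 1)
  expect_error(generate_cohort(cfg, seed = 1), "not fully inside")
})

test_that("write_cohort/read_cohort round-trips volumes, metadata, and truth", {
  cfg <- quick_cohort_config()
  ch <- generate_cohort(cfg, seed = 5)
  dir <- withr::local_tempdir()
  mp <- write_cohort(ch, dir)
  manifest <- jsonlite::read_json(mp, simplifyVector = TRUE)
  for (f in unlist(manifest$files))
    expect_true(file.exists(file.path(dir, f)))
  expect_equal(manifest$seed, 5)
  meta <- read.csv(file.path(dir, "metadata.csv"))
  expect_equal(names(meta), c("subject_id", "group", "age_years", "sex",
                              "mdrt_left_gy", "mdrt_right_gy",
                              "rt_to_scan_months"))
  expect_equal(nrow(meta), nrow(ch$subjects))
  back <- read_cohort(dir)
  expect_equal(back$bold[[2]]$data, ch$bold[[2]]$data)
  expect_equal(back$gm[[3]]$values, ch$gm[[3]]$values)
  expect_equal(back$grid$mask, ch$grid$mask)
  expect_equal(back$subjects$mdrt_left_gy, ch$subjects$mdrt_left_gy)
  expect_equal(sort(unlist(back$truth$effect_clusters[[1]]$voxels)),
               sort(unlist(ch$truth$effect_clusters[[1]]$voxels)))
})

test_that("injected effects are localized: no group shift outside the spread-out clusters", {
  dc <- default_cohort()
  ch <- dc$cohort; cm <- dc$coupling
  subj <- ch$subjects
  # dilate injected clusters (and dose regions) by the smoothing support
  excl <- array(FALSE, dim = ch$grid$shape)
  for (cl in ch$truth$effect_clusters) excl[unlist(cl$voxels)] <- TRUE
  for (dr in ch$truth$dose_regions) excl[unlist(dr$voxels)] <- TRUE
  for (rep_ in 1:3) {
    grown <- excl
    vox <- which(excl, arr.ind = TRUE)
    for (r in seq_len(nrow(vox))) {
      nb <- neighborhood(vox[r, ], ch$grid, 26)
      grown[nb] <- TRUE
    }
    excl <- grown
  }
  outside <- cm$mask & !excl
  mean_map <- function(g) {
    ms <- cm$maps[subj$group == g]
    Reduce(`+`, lapply(ms, function(m) m$values)) / length(ms)
  }
  d_outside <- mean_map("post_rt_re_pos")[outside] - mean_map("pre_rt")[outside]
  # Monte-Carlo error of a mean difference between n=22 and n=18 subjects
  expect_lt(abs(mean(d_outside)), 0.1)
  d_inside <- mean_map("post_rt_re_pos") - mean_map("pre_rt")
  pos_cl <- unlist(ch$truth$effect_clusters[[1]]$voxels)
  neg_cl <- unlist(ch$truth$effect_clusters[[2]]$voxels)
  expect_gt(mean(d_inside[pos_cl]), 0.6)   # injected +1.2 z, smoothed
  expect_lt(mean(d_inside[neg_cl]), -0.6)  # injected -1.2 z, smoothed
})
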