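#' Configuration for the synthetic NPC cohort generator
#'
#' Defaults emulate the study conditions of the radiotherapy cohort the
#' package targets: three groups (pre-RT n = 22, post-RT without radiation
#' encephalopathy n = 22, post-RT with RE n = 18; 62 subjects), BOLD series
#' with 6-mm spatially autocorrelated noise plus per-region shared temporal
#' components (the mixing weight sets local concordance, hence ReHo),
#' gray-matter maps in [0, 1] from a shared template plus subject noise,
#' group effects injected in coupling-z units at known clusters, and
#' per-hemisphere maximum radiotherapy doses ~ Normal(66, 8) Gy truncated at
#' 0 with a negative dose-coupling slope in designated temporal regions.
#' Ages ~ Normal(44, 9); sex counts 18/4, 16/6, 14/4 male/female per group;
#' doses missing for 3 of 22 RE-negative and 10 of 18 RE-positive subjects;
#' RT-to-scan intervals ~ truncated Normal(10.8, 9.7) and (17.0, 17.6)
#' months. Effect-cluster centers/radii are in voxel units on the default
#' 24 x 28 x 24 grid at 3 mm (a desk-scale stand-in for the acquisition
#' matrix); all lie inside the ellipsoidal analysis mask.
#'
#' @param grid_shape integer length-3 array dimensions.
#' @param voxel_size_mm voxel edge lengths (mm).
#' @param n_timepoints BOLD series length (>= 10; default 60).
#' @param tr_seconds repetition time (default 2.4 s).
#' @param n_per_group named integer vector over the three groups.
#' @param base_concordance baseline shared-component mixing weight.
#' @param noise_fwhm_mm spatial FWHM of the BOLD noise field (mm).
#' @param high_reho_regions list of `list(center, radius_vox, concordance)`
#'   spheres with elevated local coherence.
#' @param effect_clusters list of `list(name, center, radius_vox, effects)`
#'   where `effects` is a named per-group offset in coupling-z units.
#' @param dose_slope_z_per_gy slope of the dose effect on coupling
#'   (z units per Gy; negative by default).
#' @param dose_mean_gy,dose_sd_gy dose distribution (Gy).
#' @param n_missing_dose named vector: subjects per post-RT group with
#'   unrecorded doses.
#' @param gm_base,gm_amplitude,gm_template_fwhm_mm,gm_subject_sd,gm_noise_fwhm_mm
#'   gray-matter template level, spatial amplitude/scale, and subject noise.
#' @param effect_mode `"both"` (default: half the effect through the GM
#'   denominator, half through temporal concordance), `"gm"`, or
#'   `"concordance"`.
#' @param age_mean,age_sd age distribution (years).
#' @param reho_params,coupling_params analysis parameters used downstream
#'   (also used by the generator's internal calibration).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(grid_shape = c(24L, 28L, 24L),
                          voxel_size_mm = c(3, 3, 3),
                          n_timepoints = 60L,
                          tr_seconds = 2.4,
                          n_per_group = c(pre_rt = 22L, post_rt_re_neg = 22L,
                                          post_rt_re_pos = 18L),
                          base_concordance = 0.3,
                          noise_fwhm_mm = 6,
                          high_reho_regions = NULL,
                          effect_clusters = NULL,
                          dose_slope_z_per_gy = -0.04,
                          dose_mean_gy = 66, dose_sd_gy = 8,
                          n_missing_dose = c(post_rt_re_neg = 3L,
                                             post_rt_re_pos = 10L),
                          gm_base = 0.55, gm_amplitude = 0.12,
                          gm_template_fwhm_mm = 9, gm_subject_sd = 0.03,
                          gm_noise_fwhm_mm = 6,
                          effect_mode = c("both", "gm", "concordance"),
                          age_mean = 44, age_sd = 9,
                          reho_params = sfcouple::reho_params(),
                          coupling_params = sfcouple::coupling_params()) {
  effect_mode <- match.arg(effect_mode)
  grid_shape <- as.integer(grid_shape)
  ctr <- (grid_shape + 1) / 2
  if (is.null(high_reho_regions)) {
    high_reho_regions <- list(
      list(center = round(ctr + c(0, grid_shape[2] * 0.18, grid_shape[3] * 0.12)),
           radius_vox = 3, concordance = 0.55))
  }
  if (is.null(effect_clusters)) {
    effect_clusters <- list(
      # deep gray matter: coupling increases after RT
      list(name = "deep_gray", center = round(ctr + c(0, 0, 1)),
           radius_vox = 2.5,
           effects = c(pre_rt = 0, post_rt_re_neg = 0.5, post_rt_re_pos = 1.2)),
      # medial temporal: coupling decreases after RT
      list(name = "medial_temporal",
           center = round(ctr + c(-grid_shape[1] * 0.2, -grid_shape[2] * 0.12,
                                  -grid_shape[3] * 0.22)),
           radius_vox = 2.5,
           effects = c(pre_rt = 0, post_rt_re_neg = -0.5, post_rt_re_pos = -1.2)))
  }
  sex_counts <- list(pre_rt = c(male = 18L, female = 4L),
                     post_rt_re_neg = c(male = 16L, female = 6L),
                     post_rt_re_pos = c(male = 14L, female = 4L))
  interval_pars <- list(post_rt_re_neg = c(mean = 10.77, sd = 9.74),
                        post_rt_re_pos = c(mean = 17.00, sd = 17.61))
  # dose-correlated temporal regions, one per hemisphere (left = low i)
  dose_regions <- list(
    left = list(center = round(c(grid_shape[1] * 0.27, ctr[2] - 2,
                                 grid_shape[3] * 0.3)), radius_vox = 2.5),
    right = list(center = round(c(grid_shape[1] * 0.73, ctr[2] - 2,
                                  grid_shape[3] * 0.3)), radius_vox = 2.5))
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 n_timepoints = as.integer(n_timepoints),
                 tr_seconds = tr_seconds, n_per_group = n_per_group,
                 base_concordance = base_concordance,
                 noise_fwhm_mm = noise_fwhm_mm,
                 high_reho_regions = high_reho_regions,
                 effect_clusters = effect_clusters,
                 dose_regions = dose_regions,
                 dose_slope_z_per_gy = dose_slope_z_per_gy,
                 dose_mean_gy = dose_mean_gy, dose_sd_gy = dose_sd_gy,
                 n_missing_dose = n_missing_dose,
                 gm_base = gm_base, gm_amplitude = gm_amplitude,
                 gm_template_fwhm_mm = gm_template_fwhm_mm,
                 gm_subject_sd = gm_subject_sd,
                 gm_noise_fwhm_mm = gm_noise_fwhm_mm,
                 effect_mode = effect_mode,
                 age_mean = age_mean, age_sd = age_sd,
                 sex_counts = sex_counts, interval_pars = interval_pars,
                 reho_params = reho_params,
                 coupling_params = coupling_params),
            class = "cohort_config")
}

group_levels <- function() c("pre_rt", "post_rt_re_neg", "post_rt_re_pos")

sphere_mask <- function(shape, center, radius) {
  ii <- array(rep(seq_len(shape[1]), times = shape[2] * shape[3]), dim = shape)
  jj <- array(rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]),
              dim = shape)
  kk <- array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), dim = shape)
  (ii - center[1])^2 + (jj - center[2])^2 + (kk - center[3])^2 <= radius^2
}

ellipsoid_mask <- function(shape, margin = 1) {
  ctr <- (shape + 1) / 2
  semi <- shape / 2 - margin
  ii <- array(rep(seq_len(shape[1]), times = shape[2] * shape[3]), dim = shape)
  jj <- array(rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]),
              dim = shape)
  kk <- array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), dim = shape)
  ((ii - ctr[1]) / semi[1])^2 + ((jj - ctr[2]) / semi[2])^2 +
    ((kk - ctr[3]) / semi[3])^2 <= 1
}

# hemisphere temporal-lobe boxes: inferior 40% of slices, lateral 40% of i.
temporal_masks <- function(shape, mask) {
  tl <- array(FALSE, dim = shape); tr_ <- array(FALSE, dim = shape)
  k_hi <- ceiling(shape[3] * 0.4)
  i_lo <- ceiling(shape[1] * 0.4)
  tl[seq_len(i_lo), , seq_len(k_hi)] <- TRUE
  tr_[(shape[1] - i_lo + 1):shape[1], , seq_len(k_hi)] <- TRUE
  list(left = tl & mask, right = tr_ & mask)
}

rtruncnorm1 <- function(n, mean, sd, lower = 0) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lower
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lower
  }
  x
}

# Smoothed unit-variance white noise on the full grid; `sm` from smoother()
# (unmasked), `scale` the empirical renormalization so in-mask sd ~ 1.
smooth_noise_field <- function(shape, sm, scale) {
  conv3_separable(array(stats::rnorm(prod(shape)), dim = shape), sm$bands) /
    scale
}

# Empirical concordance -> expected ReHo calibration on a small block with
# the cohort's noise machinery; returns a monotone lookup table.
calibrate_concordance <- function(config, sm_scale) {
  shape <- c(9L, 9L, 9L)
  g <- image_grid(shape, config$voxel_size_mm)
  sig <- config$noise_fwhm_mm / (config$voxel_size_mm * 2 * sqrt(2 * log(2)))
  bands <- lapply(1:3, function(a) gaussian_band(shape[a], sig[a]))
  smb <- list(bands = bands)
  nt <- config$n_timepoints
  w_grid <- c(0.02, 0.15, 0.3, 0.45, 0.6, 0.75, 0.95)
  reho_grid <- vapply(w_grid, function(w) {
    s_t <- stats::rnorm(nt)
    dat <- array(0, dim = c(shape, nt))
    for (t in seq_len(nt)) {
      e <- smooth_noise_field(shape, smb, sm_scale)
      dat[, , , t] <- w * s_t[t] + (1 - w) * e
    }
    b <- bold_series(dat, g, config$tr_seconds, "cal")
    rh <- reho_map(b, params = config$reho_params)
    core <- array(FALSE, dim = shape); core[3:7, 3:7, 3:7] <- TRUE
    mean(rh$values[core])
  }, numeric(1))
  # enforce strict monotonicity for the inverse lookup
  reho_grid <- cummax(reho_grid) + (seq_along(reho_grid) - 1) * 1e-9
  list(w = w_grid, reho = reho_grid)
}

cal_w_to_reho <- function(cal, w) {
  stats::approx(cal$w, cal$reho, xout = pmin(pmax(w, min(cal$w)), max(cal$w)),
                rule = 2)$y
}

cal_reho_to_w <- function(cal, r) {
  stats::approx(cal$reho, cal$w, xout = pmin(pmax(r, min(cal$reho)),
                                             max(cal$reho)), rule = 2)$y
}

#' Generate a ground-truthed synthetic cohort
#'
#' See [cohort_config] for what is emulated. The generator is fully
#' reproducible from `seed`: two calls with the same config and seed return
#' bit-identical cohorts. Effects are injected in coupling-z units; the
#' z-unit scale is calibrated from a reference subject's baseline coupling
#' map (its in-mask SD) generated internally, and the concordance half of
#' each effect goes through an empirically calibrated concordance-to-ReHo
#' response curve.
#'
#' @param config a [cohort_config].
#' @param seed integer seed.
#' @return list of class `synthetic_cohort`: `subjects` (metadata
#'   data.frame), `bold` (list of [bold_series]), `gm` (list of
#'   `scalar_map`s), `grid` (with the analysis mask), `temporal_masks`
#'   (left/right logical arrays), `truth` (effect masks, per-group z
#'   offsets, dose regions and slope, calibration), `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  shape <- config$grid_shape
  mask <- ellipsoid_mask(shape)
  grid <- image_grid(shape, config$voxel_size_mm, mask = mask)
  for (cl in config$effect_clusters) {
    if (!all(mask[sphere_mask(shape, cl$center, cl$radius_vox)]))
      stop(sprintf("effect cluster '%s' is not fully inside the analysis mask",
                   cl$name))
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))

  sm_full <- smoother(image_grid(shape, config$voxel_size_mm),
                      config$noise_fwhm_mm, masked = FALSE)
  # empirical unit-variance renormalization for smoothed noise
  probe <- conv3_separable(array(stats::rnorm(prod(shape)), dim = shape),
                           sm_full$bands)
  sm_scale <- stats::sd(probe[mask])

  cal <- calibrate_concordance(config, sm_scale)

  # region/component map: 1 = background, then high-ReHo regions, effect
  # clusters and dose regions each coherent on their own component
  region <- array(1L, dim = shape)
  w_base <- array(config$base_concordance, dim = shape)
  rid <- 1L
  for (hr in config$high_reho_regions) {
    rid <- rid + 1L
    sp <- sphere_mask(shape, hr$center, hr$radius_vox)
    region[sp] <- rid
    w_base[sp] <- hr$concordance
  }
  effect_masks <- list()
  for (cl in config$effect_clusters) {
    rid <- rid + 1L
    sp <- sphere_mask(shape, cl$center, cl$radius_vox)
    region[sp] <- rid
    effect_masks[[cl$name]] <- sp
  }
  dose_masks <- list()
  for (h in names(config$dose_regions)) {
    dr <- config$dose_regions[[h]]
    rid <- rid + 1L
    sp <- sphere_mask(shape, dr$center, dr$radius_vox) & mask
    region[sp] <- rid
    dose_masks[[h]] <- sp
  }
  n_regions <- rid

  # shared gray-matter template in [0, 1]
  sm_tpl <- smoother(image_grid(shape, config$voxel_size_mm),
                     config$gm_template_fwhm_mm, masked = FALSE)
  tpl_field <- conv3_separable(array(stats::rnorm(prod(shape)), dim = shape),
                               sm_tpl$bands)
  tpl_field <- (tpl_field - mean(tpl_field[mask])) / stats::sd(tpl_field[mask])
  gm_template <- pmin(pmax(config$gm_base + config$gm_amplitude * tpl_field,
                           0.12), 0.95)
  gm_template[!mask] <- 0
  sm_gm <- smoother(image_grid(shape, config$voxel_size_mm),
                    config$gm_noise_fwhm_mm, masked = FALSE)

  # reference subject (baseline, no effects) fixes the coupling-z unit scale
  state_pre_ref <- .Random.seed
  ref <- simulate_subject_arrays(config, shape, mask, region, n_regions,
                                 w_base, gm_template, sm_full, sm_gm, sm_scale)
  state_post_ref <- .Random.seed
  ref_bold <- bold_series(ref$bold, grid, config$tr_seconds, "reference")
  ref_reho <- reho_map(ref_bold, params = config$reho_params)
  ref_gm <- scalar_map(ref$gm, grid, "gm_volume")
  ref_coupling <- coupling_ratio(ref_reho, ref_gm, config$coupling_params)
  cmask <- map_mask(ref_coupling)
  sigma_ref <- stats::sd(ref_coupling$values[cmask])
  cbar_global <- mean(ref_coupling$values[cmask])
  cbar_arr <- array(cbar_global, dim = shape)
  cluster_cbar <- list()
  for (nm in names(effect_masks)) {
    mm <- effect_masks[[nm]] & cmask
    cluster_cbar[[nm]] <- mean(ref_coupling$values[mm])
    cbar_arr[effect_masks[[nm]]] <- cluster_cbar[[nm]]
  }
  for (h in names(dose_masks)) {
    mm <- dose_masks[[h]] & cmask
    if (any(mm)) cbar_arr[dose_masks[[h]]] <- mean(ref_coupling$values[mm])
  }

  # concordance-route delivery: the block calibration overstates the ReHo
  # response at cluster boundaries (neighborhoods straddle the region edge),
  # so measure the actually delivered coupling shift with a matched-noise
  # probe subject (same RNG draws as the reference, concordance share of a
  # unit effect applied) and route any shortfall through the GM denominator.
  frac_gm <- switch(config$effect_mode, both = 0.5, gm = 1, concordance = 0)
  conc_shift <- function(dz_arr) {
    d_reho <- (1 - frac_gm) * dz_arr * sigma_ref * gm_template
    w <- w_base
    dc_conc <- dz_arr * 0
    nz <- d_reho != 0
    if (any(nz)) {
      reho_b <- cal_w_to_reho(cal, w_base[nz])
      target <- pmin(pmax(reho_b + d_reho[nz], min(cal$reho)), max(cal$reho))
      w[nz] <- cal_reho_to_w(cal, target)
      dc_conc[nz] <- (target - reho_b) / gm_template[nz]
    }
    list(w = w, dc_conc = dc_conc)
  }
  probe_masks <- c(effect_masks, dose_masks)
  probe_signs <- c(
    vapply(config$effect_clusters,
           function(cl) if (cl$effects[["post_rt_re_pos"]] >= 0) 1 else -1,
           numeric(1)),
    rep(if (config$dose_slope_z_per_gy <= 0) -1 else 1, length(dose_masks)))
  names(probe_signs) <- names(probe_masks)
  rho_arr <- array(1, dim = shape)
  if (frac_gm < 1 && length(probe_masks)) {
    dz_probe <- array(0, dim = shape)
    for (nm in names(probe_masks))
      dz_probe[probe_masks[[nm]]] <- probe_signs[[nm]]
    ps <- conc_shift(dz_probe)
    assign(".Random.seed", state_pre_ref, envir = globalenv())
    probe <- simulate_subject_arrays(config, shape, mask, region, n_regions,
                                     ps$w, gm_template, sm_full, sm_gm,
                                     sm_scale)
    assign(".Random.seed", state_post_ref, envir = globalenv())
    probe_c <- coupling_ratio(
      reho_map(bold_series(probe$bold, grid, config$tr_seconds, "probe"),
               params = config$reho_params),
      scalar_map(probe$gm, grid, "gm_volume"), config$coupling_params)
    pmask_all <- map_mask(probe_c) & cmask
    for (nm in names(probe_masks)) {
      mm <- probe_masks[[nm]] & pmask_all
      if (!any(mm)) next
      intended <- probe_signs[[nm]] * (1 - frac_gm) * sigma_ref
      achieved <- mean(probe_c$values[mm] - ref_coupling$values[mm])
      r <- achieved / intended
      rho_arr[probe_masks[[nm]]] <- min(max(r, 0), 1.2)
    }
  }

  subjects <- simulate_metadata(config)
  groups <- subjects$group

  bold <- vector("list", nrow(subjects))
  gm <- vector("list", nrow(subjects))
  for (s in seq_len(nrow(subjects))) {
    gname <- groups[s]
    # per-voxel injected offset in coupling-z units
    dz <- array(0, dim = shape)
    for (cl in config$effect_clusters)
      dz[effect_masks[[cl$name]]] <- dz[effect_masks[[cl$name]]] +
        cl$effects[[gname]]
    if (gname != "pre_rt") {
      for (h in names(dose_masks)) {
        dval <- subjects[[paste0("mdrt_", h, "_gy_true")]][s]
        dz[dose_masks[[h]]] <- dz[dose_masks[[h]]] +
          config$dose_slope_z_per_gy * (dval - config$dose_mean_gy)
      }
    }
    dc <- dz * sigma_ref
    # concordance (numerator) share through the calibrated response curve,
    # discounted by the measured boundary delivery; the GM (denominator)
    # share absorbs the remainder so the total shift is dc
    cs <- conc_shift(dz)
    w_subj <- cs$w
    # the two routes compose multiplicatively on the ratio, so solve for the
    # GM factor that makes the combined shift exactly dc
    gm_factor <- pmax(cbar_arr + rho_arr * cs$dc_conc, 0.05 * cbar_arr) /
      pmax(cbar_arr + dc, 0.05 * cbar_arr)
    arrs <- simulate_subject_arrays(config, shape, mask, region, n_regions,
                                    w_subj, gm_template, sm_full, sm_gm,
                                    sm_scale, gm_factor = gm_factor)
    bold[[s]] <- bold_series(arrs$bold, grid, config$tr_seconds,
                             subjects$subject_id[s])
    gm[[s]] <- scalar_map(arrs$gm, grid, "gm_volume",
                          meta = list(subject_id = subjects$subject_id[s]))
  }

  truth <- list(
    effect_clusters = lapply(seq_along(config$effect_clusters), function(i) {
      cl <- config$effect_clusters[[i]]
      list(name = cl$name, effects = as.list(cl$effects),
           voxels = which(effect_masks[[cl$name]]),
           sign = if (cl$effects[["post_rt_re_pos"]] >= 0) "positive" else "negative")
    }),
    dose_regions = lapply(names(dose_masks), function(h)
      list(hemisphere = h, voxels = which(dose_masks[[h]]))),
    dose_coupling_slope = config$dose_slope_z_per_gy,
    reho_structure = list(base_concordance = config$base_concordance,
                          calibration = cal),
    sigma_ref = sigma_ref, cbar_global = cbar_global, seed = as.integer(seed))

  # analyst-facing metadata: hide the true doses behind missingness
  subjects$mdrt_left_gy <- ifelse(subjects$dose_missing, NA,
                                  subjects$mdrt_left_gy_true)
  subjects$mdrt_right_gy <- ifelse(subjects$dose_missing, NA,
                                   subjects$mdrt_right_gy_true)
  meta_cols <- c("subject_id", "group", "age_years", "sex", "mdrt_left_gy",
                 "mdrt_right_gy", "rt_to_scan_months")
  structure(list(subjects = subjects[, c(meta_cols, "mdrt_left_gy_true",
                                         "mdrt_right_gy_true")],
                 bold = bold, gm = gm, grid = grid,
                 temporal_masks = temporal_masks(shape, mask),
                 truth = truth, config = config, seed = as.integer(seed)),
            class = "synthetic_cohort")
}

# one subject's raw arrays (BOLD 4D + GM 3D)
simulate_subject_arrays <- function(config, shape, mask, region, n_regions,
                                    w_arr, gm_template, sm_full, sm_gm,
                                    sm_scale, gm_factor = NULL) {
  nt <- config$n_timepoints
  s_mat <- matrix(stats::rnorm(n_regions * nt), nrow = n_regions)
  dat <- array(0, dim = c(shape, nt))
  for (t in seq_len(nt)) {
    e <- smooth_noise_field(shape, sm_full, sm_scale)
    s_arr <- array(s_mat[cbind(as.vector(region), t)], dim = shape)
    dat[, , , t] <- w_arr * s_arr + (1 - w_arr) * e
  }
  gm_noise <- conv3_separable(array(stats::rnorm(prod(shape)), dim = shape),
                              sm_gm$bands) / sm_scale
  gm <- gm_template + config$gm_subject_sd * gm_noise
  if (!is.null(gm_factor)) gm <- gm * gm_factor
  gm <- pmin(pmax(gm, 0.02), 1)
  gm[!mask] <- 0
  list(bold = dat, gm = gm)
}

simulate_metadata <- function(config) {
  rows <- list()
  for (g in group_levels()) {
    n <- config$n_per_group[[g]]
    sx <- config$sex_counts[[g]]
    if (sum(sx) != n) {   # non-default group size: keep the sex ratio
      nm <- round(n * sx[["male"]] / sum(sx))
      sx <- c(male = nm, female = n - nm)
    }
    sexes <- sample(rep(c("male", "female"), times = sx[c("male", "female")]))
    age <- rtruncnorm1(n, config$age_mean, config$age_sd, lower = 14)
    if (g == "pre_rt") {
      # pre-RT subjects carry no dose or interval at all
      dl <- rep(NA_real_, n); dr <- rep(NA_real_, n)
      iv <- rep(NA_real_, n); miss <- rep(TRUE, n)
      dlt <- rep(NA_real_, n); drt <- rep(NA_real_, n)
    } else {
      dlt <- rtruncnorm1(n, config$dose_mean_gy, config$dose_sd_gy)
      drt <- rtruncnorm1(n, config$dose_mean_gy, config$dose_sd_gy)
      ip <- config$interval_pars[[g]]
      iv <- rtruncnorm1(n, ip[["mean"]], ip[["sd"]], lower = 1)
      nmiss <- config$n_missing_dose[[g]]
      miss <- rep(FALSE, n)
      miss[sample.int(n, nmiss)] <- TRUE
      dl <- dlt; dr <- drt
    }
    rows[[g]] <- data.frame(
      subject_id = sprintf("%s_%02d", g, seq_len(n)),
      group = g, age_years = age, sex = sexes,
      mdrt_left_gy = dl, mdrt_right_gy = dr, rt_to_scan_months = iv,
      mdrt_left_gy_true = dlt, mdrt_right_gy_true = drt,
      dose_missing = miss, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("synthetic_cohort: %d subjects (%s), grid %s, T = %d, seed %d\n",
              nrow(x$subjects),
              paste(sprintf("%s = %d", names(tab), tab), collapse = ", "),
              paste(x$grid$shape, collapse = "x"),
              dim(x$bold[[1]]$data)[4], x$seed))
  cat(sprintf("  %d effect clusters, sigma_ref = %.4g\n",
              length(x$truth$effect_clusters), x$truth$sigma_ref))
  invisible(x)
}
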