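#' Estimate map smoothness (FWHM) from residual maps
#'
#' Derivative-variance estimator: each residual map is standardized within
#' the mask, first differences are taken between in-mask neighbor pairs
#' along each axis, and the per-axis FWHM is
#' `voxel_size * sqrt(4 ln 2 / var(diff))`. For a Gaussian autocorrelation
#' this recovers the smoothing FWHM; for unsmoothed voxel noise it returns
#' about 1.18 voxels (spatial structure below the grid scale is not
#' resolvable). Difference variances are pooled over maps before inversion.
#'
#' @param residual_maps list of `scalar_map`s, or a `glm_result` with stored
#'   residuals; at least 2 maps/columns.
#' @param mask optional mask overriding the maps' analysis mask.
#' @return numeric length-3 FWHM in mm (i, j, k axes).
#' @export
estimate_smoothness <- function(residual_maps, mask = NULL) {
  if (inherits(residual_maps, "glm_result")) {
    gr <- residual_maps
    if (is.null(gr$residuals))
      stop("glm_result was fitted with keep_residuals = FALSE")
    grid <- gr$grid
    if (is.null(mask)) mask <- gr$mask
    nmaps <- ncol(gr$residuals)
    get_map <- function(j) {
      a <- array(0, dim = grid$shape); a[mask] <- gr$residuals[, j]; a
    }
  } else {
    if (length(residual_maps) < 2)
      stop("estimate_smoothness needs at least 2 residual maps")
    grid <- residual_maps[[1]]$grid
    if (is.null(mask)) mask <- map_mask(residual_maps[[1]])
    nmaps <- length(residual_maps)
    get_map <- function(j) residual_maps[[j]]$values
  }
  if (nmaps < 2) stop("estimate_smoothness needs at least 2 residual maps")
  ss <- c(0, 0, 0); nn <- c(0, 0, 0)
  sh <- grid$shape
  pair_mask <- list(
    mask[-sh[1], , ] & mask[-1, , ],
    mask[, -sh[2], ] & mask[, -1, ],
    mask[, , -sh[3]] & mask[, , -1])
  for (j in seq_len(nmaps)) {
    a <- get_map(j)
    x <- a[mask]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("estimate_smoothness: constant residual map; smoothness undefined")
    a <- (a - mean(x)) / s
    d1 <- (a[-1, , ] - a[-sh[1], , ])[pair_mask[[1]]]
    d2 <- (a[, -1, ] - a[, -sh[2], ])[pair_mask[[2]]]
    d3 <- (a[, , -1] - a[, , -sh[3]])[pair_mask[[3]]]
    ss <- ss + c(sum(d1^2), sum(d2^2), sum(d3^2))
    nn <- nn + c(length(d1), length(d2), length(d3))
  }
  vd <- ss / nn
  if (any(vd <= 0)) stop("estimate_smoothness: degenerate difference variance")
  grid$voxel_size_mm * sqrt(4 * log(2) / vd)
}

#' Monte-Carlo cluster-extent threshold (alphasim)
#'
#' Estimates the minimum cluster size controlling the cluster-level false
#' positive rate: in each iteration, white Gaussian noise is generated on
#' the analysis mask, smoothed to the estimated map FWHM (masked, with
#' renormalization), standardized within the mask, thresholded two-tailed at
#' `voxel_p`, and the maximum cluster size over positive and negative
#' suprathreshold voxels (clustered separately) is recorded. The threshold
#' `k` is the smallest cluster size whose exceedance frequency is at most
#' `cluster_alpha`.
#'
#' @param grid `image_grid` carrying the analysis mask.
#' @param est_fwhm_mm length-3 (or scalar) smoothness in mm, e.g. from
#'   [estimate_smoothness].
#' @param voxel_p two-tailed voxel-level threshold (default 0.001).
#' @param cluster_alpha cluster-level alpha (default 0.01).
#' @param n_iter Monte-Carlo iterations (>= 100; default 1000).
#' @param connectivity cluster-forming connectivity (default 26).
#' @param seed integer seed; the run is reproducible from it.
#' @return object of class `alphasim_result`: `k_threshold_voxels`,
#'   `max_cluster_null` (length `n_iter`), plus the settings.
#' @export
alphasim_threshold <- function(grid, est_fwhm_mm, voxel_p = 0.001,
                               cluster_alpha = 0.01, n_iter = 1000,
                               connectivity = 26, seed = 1L) {
  stopifnot(n_iter >= 100, voxel_p > 0, voxel_p < 1,
            cluster_alpha > 0, cluster_alpha <= 1)
  est_fwhm_mm <- rep(as.numeric(est_fwhm_mm), length.out = 3)
  mask <- grid$mask
  v <- sum(mask)
  fwhm_iso <- mean(est_fwhm_mm)
  if (any(grid$shape * grid$voxel_size_mm < 2 * fwhm_iso))
    warning("alphasim_threshold: mask extent is small relative to the smoothing kernel")
  sm <- if (fwhm_iso > 0) {
    sig <- est_fwhm_mm / (grid$voxel_size_mm * 2 * sqrt(2 * log(2)))
    bands <- lapply(1:3, function(a) gaussian_band(grid$shape[a], sig[a]))
    smm <- conv3_separable(array(as.numeric(mask), dim = grid$shape), bands)
    smm[smm <= 0] <- 1
    list(bands = bands, sm_mask = smm)
  } else NULL
  zthr <- stats::qnorm(1 - voxel_p / 2)
  max_null <- integer(n_iter)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  for (it in seq_len(n_iter)) {
    noise <- array(0, dim = grid$shape)
    noise[mask] <- stats::rnorm(v)
    if (!is.null(sm)) {
      noise <- conv3_separable(noise, sm$bands) / sm$sm_mask
    }
    x <- noise[mask]
    z <- array(0, dim = grid$shape)
    z[mask] <- (x - mean(x)) / stats::sd(x)
    mx <- 0L
    for (sgn in c(1, -1)) {
      supra <- (sgn * z > zthr) & mask
      ns <- sum(supra)
      if (ns == 0L) next
      if (ns == 1L) { mx <- max(mx, 1L); next }
      cl <- label_clusters(supra, grid, connectivity)
      mx <- max(mx, max(cl$table$n_voxels))
    }
    max_null[it] <- mx
  }
  # smallest k with P(max cluster >= k) <= cluster_alpha
  k <- 1L
  while (mean(max_null >= k) > cluster_alpha) k <- k + 1L
  structure(list(est_fwhm_mm = est_fwhm_mm, n_iterations = n_iter,
                 voxel_p = voxel_p, cluster_alpha = cluster_alpha,
                 max_cluster_null = max_null, k_threshold_voxels = k,
                 connectivity = connectivity, seed = as.integer(seed)),
            class = "alphasim_result")
}

#' @export
print.alphasim_result <- function(x, ...) {
  cat(sprintf(paste0("alphasim_result: k >= %d voxels (voxel p < %g two-tailed,",
                     " cluster alpha %g, %d iterations, FWHM %.2f/%.2f/%.2f mm)\n"),
              x$k_threshold_voxels, x$voxel_p, x$cluster_alpha, x$n_iterations,
              x$est_fwhm_mm[1], x$est_fwhm_mm[2], x$est_fwhm_mm[3]))
  invisible(x)
}

#' Apply Monte-Carlo cluster-extent correction to a GLM contrast
#'
#' Voxels with two-tailed p below the alphasim voxel threshold are clustered
#' (positive and negative t separately, under the alphasim connectivity);
#' clusters at least as large as the Monte-Carlo extent threshold survive.
#'
#' @param glm a `glm_result`.
#' @param alphasim an `alphasim_result` computed on the same grid/mask.
#' @return a `cluster_report` data.frame: cluster_id, n_voxels, size_mm3,
#'   peak_t, i, j, k (0-based voxel indices), x_mm, y_mm, z_mm (MNI), sign.
#' @export
apply_cluster_correction <- function(glm, alphasim) {
  report_clusters(glm, voxel_p = alphasim$voxel_p,
                  k_min = alphasim$k_threshold_voxels,
                  connectivity = alphasim$connectivity)
}

# Shared cluster-report builder: threshold |p| < voxel_p, split by sign of
# t, keep clusters of size >= k_min.
report_clusters <- function(glm, voxel_p, k_min = 1L, connectivity = 26,
                            significant = NULL) {
  grid <- glm$grid
  rows <- list()
  cid <- 0L
  for (sgn in c(1, -1)) {
    supra <- if (is.null(significant)) {
      glm$p_map$values < voxel_p & glm$mask
    } else significant & glm$mask
    supra <- supra & (sgn * glm$t_map$values > 0)
    if (!any(supra)) next
    cl <- label_clusters(supra, grid, connectivity)
    keep <- cl$table$n_voxels >= k_min
    for (id in cl$table$cluster_id[keep]) {
      vox <- which(cl$labels == id, arr.ind = TRUE)
      tv <- glm$t_map$values[cl$labels == id]
      pk <- which.max(abs(tv))
      pk_ijk <- vox[pk, ]
      mm <- voxel_to_mm(pk_ijk, grid)
      cid <- cid + 1L
      rows[[cid]] <- data.frame(
        cluster_id = cid, n_voxels = nrow(vox),
        size_mm3 = nrow(vox) * prod(grid$voxel_size_mm),
        peak_t = tv[pk],
        i = pk_ijk[1] - 1L, j = pk_ijk[2] - 1L, k = pk_ijk[3] - 1L,
        x_mm = mm[1], y_mm = mm[2], z_mm = mm[3],
        sign = if (sgn > 0) "positive" else "negative")
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(), n_voxels = integer(),
               size_mm3 = numeric(), peak_t = numeric(), i = integer(),
               j = integer(), k = integer(), x_mm = numeric(),
               y_mm = numeric(), z_mm = numeric(), sign = character())
  if (nrow(out)) {
    out <- out[order(-out$n_voxels), , drop = FALSE]
    out$cluster_id <- seq_len(nrow(out))
    rownames(out) <- NULL
  }
  class(out) <- c("cluster_report", "data.frame")
  out
}

#' Report clusters of FDR-significant voxels
#'
#' Convenience wrapper: clusters the reject set of [fdr_correct] (split by
#' effect sign) with an optional minimum extent.
#'
#' @param glm a `glm_result`.
#' @param fdr result of [fdr_correct] on `glm$p_map`.
#' @param k_min minimum cluster extent in voxels (default 1).
#' @param connectivity cluster-forming connectivity.
#' @return a `cluster_report` data.frame.
#' @export
fdr_cluster_report <- function(glm, fdr, k_min = 1L, connectivity = 26) {
  report_clusters(glm, voxel_p = NA, k_min = k_min,
                  connectivity = connectivity, significant = fdr$significant)
}

#' Voxelwise dose-coupling Pearson correlation within the temporal lobes
#'
#' For one hemisphere, correlates each temporal-lobe voxel's coupling value
#' with that hemisphere's maximum radiotherapy dose (MDRT, Gy) across the
#' subjects with a recorded dose (pairwise deletion of missing doses, the
#' default; `listwise = TRUE` restricts to subjects with both hemisphere
#' doses). Two-tailed p from `t = r sqrt((n-2)/(1-r^2))`; BH-FDR at `q`
#' over the hemisphere mask.
#'
#' @param maps list of `coupling_z` maps (post-RT subjects), aligned with
#'   `subjects` rows.
#' @param subjects data.frame with `mdrt_left_gy`, `mdrt_right_gy`.
#' @param hemisphere `"left"` or `"right"`.
#' @param temporal_mask logical array (that hemisphere's temporal lobe).
#' @param q FDR level (default 0.05).
#' @param listwise drop subjects missing either hemisphere's dose.
#' @return list: `r_map`, `p_map` (`scalar_map`s), `significant` (logical
#'   array), `n_subjects`, `p_threshold`.
#' @export
dose_correlation <- function(maps, subjects, hemisphere = c("left", "right"),
                             temporal_mask, q = 0.05, listwise = FALSE) {
  hemisphere <- match.arg(hemisphere)
  dose <- if (hemisphere == "left") subjects$mdrt_left_gy else subjects$mdrt_right_gy
  keep <- !is.na(dose)
  if (listwise) keep <- keep & !is.na(subjects$mdrt_left_gy) &
      !is.na(subjects$mdrt_right_gy)
  if (sum(keep) < 5)
    stop("dose_correlation: fewer than 5 subjects with a recorded dose")
  dose <- dose[keep]
  if (stats::sd(dose) == 0)
    stop("dose_correlation: zero dose variance; correlation undefined")
  maps <- maps[keep]
  grid <- maps[[1]]$grid
  m <- temporal_mask & intersection_mask(maps)
  if (!any(m)) stop("dose_correlation: empty temporal analysis mask")
  n <- length(dose)
  Y <- vapply(maps, function(x) x$values[m], numeric(sum(m)))  # V x n
  r <- as.vector(suppressWarnings(stats::cor(dose, t(Y))))
  r[is.na(r)] <- 0                       # zero-variance voxels: no evidence
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), n - 2)
  p[abs(r) >= 1] <- 0
  adj <- stats::p.adjust(p, method = "BH")
  rej <- adj <= q
  r_arr <- array(0, dim = grid$shape); r_arr[m] <- r
  p_arr <- array(1, dim = grid$shape); p_arr[!grid$mask] <- 0; p_arr[m] <- p
  sig <- array(FALSE, dim = grid$shape); sig[m] <- rej
  list(r_map = scalar_map(r_arr, grid, "rvalue",
                          meta = list(mask = m, hemisphere = hemisphere)),
       p_map = scalar_map(p_arr, grid, "pvalue", meta = list(mask = m)),
       significant = sig, n_subjects = n,
       p_threshold = if (any(rej)) max(p[rej]) else NA_real_)
}
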