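#' Parameters for the ReHo/VBM coupling map
#'
#' @param gm_floor minimum gray-matter volume for a voxel to enter the
#'   coupling mask (default 0.1, the usual absolute VBM threshold);
#'   prevents the ratio from blowing up in non-gray-matter voxels.
#' @param transform variance-stabilizing transform applied per subject:
#'   `"zscore_in_mask"` (default) standardizes within the coupling mask;
#'   `"atanh"` applies Fisher's atanh after clipping to
#'   `[-1 + 1e-6, 1 - 1e-6]` (the literal reading; values >= 1 are clipped
#'   and the clip count logged in `meta`).
#' @param smooth_fwhm_mm isotropic Gaussian smoothing FWHM in mm applied
#'   after the transform (default 6).
#' @return list of class `coupling_params`.
#' @export
coupling_params <- function(gm_floor = 0.1,
                            transform = c("zscore_in_mask", "atanh"),
                            smooth_fwhm_mm = 6) {
  transform <- match.arg(transform)
  stopifnot(gm_floor > 0, gm_floor < 1, smooth_fwhm_mm >= 0)
  structure(list(gm_floor = gm_floor, transform = transform,
                 smooth_fwhm_mm = smooth_fwhm_mm), class = "coupling_params")
}

#' Voxelwise ReHo / gray-matter-volume ratio
#'
#' The structure-function coupling metric: ReHo divided by the modulated
#' gray-matter volume at the same coordinate. Voxels whose GM volume falls
#' below `gm_floor` are removed from the coupling mask (recorded in
#' `meta$mask` and counted in `meta$n_gm_excluded`); the output contains no
#' infinities or NaN.
#'
#' @param reho `scalar_map` of kind `"reho"`.
#' @param gm `scalar_map` of kind `"gm_volume"` on the same grid.
#' @param params a [coupling_params].
#' @return `scalar_map` of kind `"coupling"`.
#' @export
coupling_ratio <- function(reho, gm, params = coupling_params()) {
  if (!grids_equal(reho$grid, gm$grid))
    stop("coupling_ratio: reho and gm grids differ")
  m <- map_mask(reho) & map_mask(gm)
  keep <- m & (gm$values >= params$gm_floor)
  vals <- array(0, dim = reho$grid$shape)
  vals[keep] <- reho$values[keep] / gm$values[keep]
  scalar_map(vals, reho$grid, kind = "coupling",
             meta = list(mask = keep, n_gm_excluded = sum(m) - sum(keep),
                         gm_floor = params$gm_floor))
}

#' Variance-stabilizing transform of a coupling map
#'
#' Default is per-subject z-standardization within the coupling mask
#' (mean 0, SD 1 in-mask). The `"atanh"` variant applies Fisher's
#' transformation literally after clipping the ratio into the atanh domain;
#' the number of clipped voxels is logged in `meta$n_clipped`.
#'
#' @param coupling `scalar_map` of kind `"coupling"`.
#' @param params a [coupling_params].
#' @return `scalar_map` of kind `"coupling_z"`.
#' @export
transform_coupling <- function(coupling, params = coupling_params()) {
  m <- map_mask(coupling)
  x <- coupling$values[m]
  meta <- coupling$meta
  if (params$transform == "zscore_in_mask") {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      warning("transform_coupling: zero in-mask variance; returning all-zero map")
      z <- rep(0, length(x))
    } else z <- (x - mean(x)) / s
    meta$transform <- "zscore_in_mask"
  } else {
    eps <- 1e-6
    clipped <- x < -1 + eps | x > 1 - eps
    z <- atanh(pmin(pmax(x, -1 + eps), 1 - eps))
    meta$transform <- "atanh"
    meta$n_clipped <- sum(clipped)
  }
  vals <- array(0, dim = coupling$grid$shape)
  vals[m] <- z
  scalar_map(vals, coupling$grid, kind = "coupling_z", meta = meta)
}

# Column-normalized 1D Gaussian band matrix for one axis: each column sums
# to 1, so convolution preserves total mass even at the array edge.
gaussian_band <- function(len, sigma_vox, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, ceiling(6 * sigma_vox))
  d <- abs(outer(seq_len(len), seq_len(len), "-"))
  B <- exp(-d^2 / (2 * sigma_vox^2))
  B[d > radius] <- 0
  sweep(B, 2, colSums(B), "/")
}

# Apply per-axis band matrices to a 3D array by unfolding.
conv3_separable <- function(arr, bands) {
  d <- dim(arr)
  x <- matrix(arr, nrow = d[1])
  x <- bands[[1]] %*% x
  arr <- array(x, dim = d)
  arr <- aperm(arr, c(2, 1, 3))
  x <- bands[[2]] %*% matrix(arr, nrow = d[2])
  arr <- aperm(array(x, dim = d[c(2, 1, 3)]), c(2, 1, 3))
  arr <- aperm(arr, c(3, 1, 2))
  x <- bands[[3]] %*% matrix(arr, nrow = d[3])
  aperm(array(x, dim = d[c(3, 1, 2)]), c(2, 3, 1))
}

# Precompute the smoothing operator for a grid + fwhm; smoothed mask cached
# for masked renormalization.
smoother <- function(grid, fwhm_mm, masked = TRUE) {
  if (fwhm_mm == 0) return(NULL)
  sig <- fwhm_mm / (grid$voxel_size_mm * 2 * sqrt(2 * log(2)))
  bands <- lapply(1:3, function(a) gaussian_band(grid$shape[a], sig[a]))
  sm_mask <- NULL
  if (masked) {
    sm_mask <- conv3_separable(array(as.numeric(grid$mask), dim = grid$shape),
                               bands)
    sm_mask[sm_mask <= 0] <- 1   # outside support of the mask; output is 0 there
  }
  list(bands = bands, sm_mask = sm_mask)
}

apply_smoother <- function(values, grid, sm, masked = TRUE) {
  if (is.null(sm)) return(values)
  if (masked) {
    out <- conv3_separable(values * grid$mask, sm$bands) / sm$sm_mask
    out[!grid$mask] <- 0
    out
  } else {
    conv3_separable(values, sm$bands)
  }
}

#' Gaussian smoothing of a scalar map
#'
#' Separable isotropic Gaussian smoothing with
#' `sigma_voxels = fwhm / (voxel_size * 2 sqrt(2 ln 2))` per axis. By
#' default smoothing is restricted to the mask and renormalized by the
#' smoothed mask, so no signal bleeds in from the outside-mask zeros and a
#' constant in-mask map stays constant. `fwhm_mm = 0` returns the input
#' unchanged. Unmasked smoothing (`masked = FALSE`) preserves the array sum
#' (edge columns of the kernel are renormalized to unit mass).
#'
#' @param map a `scalar_map`.
#' @param fwhm_mm full width at half maximum in mm.
#' @param masked restrict and renormalize within the map's analysis mask.
#' @return smoothed `scalar_map` (same kind).
#' @export
smooth_map <- function(map, fwhm_mm, masked = TRUE) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(map)
  grid <- map$grid
  g <- if (masked) {
    image_grid(grid$shape, grid$voxel_size_mm, grid$affine, map_mask(map))
  } else {
    image_grid(grid$shape, grid$voxel_size_mm, grid$affine)
  }
  sm <- smoother(g, fwhm_mm, masked = masked)
  out <- apply_smoother(map$values, g, sm, masked = masked)
  meta <- map$meta
  meta$smooth_fwhm_mm <- fwhm_mm
  kind <- if (map$kind %in% c("reho", "pvalue")) "generic" else map$kind
  scalar_map(out, grid, kind = kind, meta = meta)
}

#' Per-subject coupling pipeline
#'
#' ReHo, then the ReHo/GM ratio, then the variance-stabilizing transform,
#' then masked Gaussian smoothing — in that order (the transform precedes
#' the smoothing). Deterministic given its inputs.
#'
#' @param bold a [bold_series].
#' @param gm `scalar_map` of kind `"gm_volume"` on the same grid.
#' @param mask optional analysis mask.
#' @param reho_params a [reho_params].
#' @param coupling_params a [coupling_params].
#' @return `scalar_map` of kind `"coupling_z"` (smoothed).
#' @export
subject_coupling_pipeline <- function(bold, gm, mask = NULL,
                                      reho_params = sfcouple::reho_params(),
                                      coupling_params = sfcouple::coupling_params()) {
  rh <- reho_map(bold, mask = mask, params = reho_params)
  cp <- coupling_ratio(rh, gm, params = coupling_params)
  cz <- transform_coupling(cp, params = coupling_params)
  smooth_map(cz, coupling_params$smooth_fwhm_mm, masked = TRUE)
}

#' Intersection coupling mask across subjects
#'
#' Group analyses require every subject observed at every analyzed voxel;
#' this returns the intersection of the subjects' coupling masks.
#'
#' @param maps list of `scalar_map`s with `meta$mask` set.
#' @return logical array.
#' @export
intersection_mask <- function(maps) {
  m <- map_mask(maps[[1]])
  for (x in maps[-1]) m <- m & map_mask(x)
  if (!any(m)) stop("intersection_mask: empty intersection")
  m
}
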