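#' Parameters for regional homogeneity
#'
#' @param connectivity neighborhood scheme: 6, 18, or 26 (default 26, i.e.
#'   the 27-voxel cube used by the classic ReHo definition).
#' @param min_neighbors minimum number of in-mask neighbors for a voxel to
#'   receive a ReHo value (default 7); voxels below this get 0 and are
#'   counted in the output `meta`. Computing with the available in-mask
#'   neighbors, rather than requiring the full shell, keeps the cortical rim
#'   in the analysis.
#' @param tie_policy `"midrank_no_correction"` (default, the behavior of the
#'   widely used ReHo toolchains) or `"midrank_with_correction"` (applies
#'   the tie-correction term to the denominator of Kendall's W).
#' @return list of class `reho_params`.
#' @export
reho_params <- function(connectivity = 26, min_neighbors = 7,
                        tie_policy = c("midrank_no_correction",
                                       "midrank_with_correction")) {
  tie_policy <- match.arg(tie_policy)
  connectivity <- as.integer(connectivity)
  stopifnot(connectivity %in% c(6L, 18L, 26L))
  min_neighbors <- as.integer(min_neighbors)
  if (min_neighbors > connectivity)
    stop("min_neighbors cannot exceed the connectivity")
  structure(list(connectivity = connectivity, min_neighbors = min_neighbors,
                 tie_policy = tie_policy), class = "reho_params")
}

#' Kendall's coefficient of concordance
#'
#' W over K series of length n: each series is ranked over time (mid-ranks
#' for ties), the rank sums R_t are formed across series at each time point,
#' and
#' \deqn{W = \frac{\sum_t (R_t - \bar R)^2}{K^2 (n^3 - n)/12}}
#' with \eqn{\bar R = K(n+1)/2}. Under
#' `tie_policy = "midrank_with_correction"` the denominator becomes
#' \eqn{(K^2 (n^3 - n) - K \sum_j T_j)/12} with the usual tie term
#' \eqn{T_j = \sum (t^3 - t)} over tie groups of series j. W = 1 means all
#' series rank every time point identically; W = 0 means the rank sums are
#' constant over time. A constant series contributes all-equal mid-ranks,
#' which deflates W rather than erroring.
#'
#' @param series matrix with K rows (series) and n columns (time points),
#'   K >= 2, n >= 3.
#' @param tie_policy see [reho_params].
#' @return W in [0, 1].
#' @export
kendalls_w <- function(series, tie_policy = "midrank_no_correction") {
  series <- as.matrix(series)
  k <- nrow(series); n <- ncol(series)
  if (k < 2L) stop("kendalls_w needs at least 2 series")
  if (n < 3L) stop("kendalls_w needs at least 3 time points")
  rk <- t(apply(series, 1, rank, ties.method = "average"))
  r_t <- colSums(rk)
  s <- sum((r_t - k * (n + 1) / 2)^2)
  denom <- k^2 * (n^3 - n) / 12
  if (tie_policy == "midrank_with_correction") {
    tj <- apply(series, 1, function(x) {
      tt <- table(x); sum(tt^3 - tt)
    })
    denom <- denom - k * sum(tj) / 12
    if (denom <= 0) return(0)  # every series fully tied
  }
  w <- s / denom
  min(max(w, 0), 1)
}

#' Voxelwise regional homogeneity map
#'
#' For every in-mask voxel with at least `min_neighbors` in-mask neighbors,
#' computes Kendall's W over the time series of the voxel and its neighbors
#' (K = 1 + number of neighbors, up to 27 series for the 26-connectivity
#' cube). Voxels with too few neighbors get 0 and are counted in
#' `meta$n_low_neighbors`. ReHo is rank-based, so any voxelwise strictly
#' monotone transform of the data (scaling, offsets) leaves the map
#' unchanged.
#'
#' @param bold a [bold_series].
#' @param mask optional logical array restricting the analysis (defaults to
#'   the grid mask); must be a subset of the grid mask.
#' @param params a [reho_params].
#' @return `scalar_map` of kind `"reho"`; `meta$mask` holds the analyzed
#'   mask, `meta$low_neighbor_mask` the skipped voxels.
#' @export
reho_map <- function(bold, mask = NULL, params = reho_params()) {
  grid <- bold$grid
  if (is.null(mask)) mask <- grid$mask
  stopifnot(all(dim(mask) == grid$shape))
  mask <- mask & grid$mask
  if (!any(mask)) stop("reho_map: empty analysis mask")
  g <- image_grid(grid$shape, grid$voxel_size_mm, grid$affine, mask)
  A <- mask_adjacency(g, connectivity = params$connectivity,
                      include_self = TRUE)
  nt <- dim(bold$data)[4]
  v <- sum(mask)
  # T x V matrix of in-mask series
  dat <- matrix(bold$data[array(mask, dim = dim(bold$data))], nrow = v)
  dat <- t(dat)                                   # now T x V
  rk <- apply(dat, 2, rank, ties.method = "average")
  rk <- matrix(rk, nrow = nt)
  s_mat <- as.matrix(rk %*% A)                    # neighborhood rank sums
  k_per <- as.numeric(Matrix::colSums(A))         # series count per voxel
  num <- colSums((s_mat - outer(rep(1, nt), k_per * (nt + 1) / 2))^2)
  denom <- k_per^2 * (nt^3 - nt) / 12
  if (params$tie_policy == "midrank_with_correction") {
    tiec <- apply(dat, 2, function(x) { tt <- table(x); sum(tt^3 - tt) })
    denom <- denom - k_per * as.numeric(tiec %*% A) / 12
    denom[denom <= 0] <- Inf
  }
  w <- pmin(pmax(num / denom, 0), 1)
  low <- (k_per - 1) < params$min_neighbors
  w[low] <- 0
  vals <- array(0, dim = grid$shape)
  vals[mask] <- w
  low_mask <- array(FALSE, dim = grid$shape)
  low_mask[mask] <- low
  scalar_map(vals, grid, kind = "reho",
             meta = list(mask = mask & !low_mask,
                         low_neighbor_mask = low_mask,
                         n_low_neighbors = sum(low),
                         params = params, subject_id = bold$subject_id))
}
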