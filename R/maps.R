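#' Voxelwise scalar map
#'
#' A `scalar_map` is one 3D statistic per voxel on an `image_grid`. Values
#' outside the analysis mask are held at 0 and excluded from every
#' statistic. The `kind` tag carries light validation: ReHo and p-value
#' maps must lie in [0, 1], gray-matter volume maps must be nonnegative.
#'
#' @param values numeric array of dimension `grid$shape`.
#' @param grid an `image_grid`.
#' @param kind one of `"reho"`, `"gm_volume"`, `"coupling"`, `"coupling_z"`,
#'   `"tstat"`, `"pvalue"`, `"rvalue"`, `"weight"`, `"generic"`.
#' @param meta free-form provenance list. `meta$mask` (logical array), when
#'   present, is an analysis sub-mask tighter than the grid mask (e.g. the
#'   coupling mask after the gray-matter floor).
#' @return object of class `scalar_map`.
#' @export
scalar_map <- function(values, grid, kind = "generic", meta = list()) {
  kind <- match.arg(kind, c("reho", "gm_volume", "coupling", "coupling_z",
                            "tstat", "pvalue", "rvalue", "weight", "generic"))
  values <- array(as.numeric(values), dim = grid$shape)
  values[!grid$mask] <- 0
  inm <- values[grid$mask]
  if (any(!is.finite(inm)))
    stop("scalar_map: non-finite values inside mask")
  tol <- 1e-9
  if (kind %in% c("reho", "pvalue")) {
    if (any(inm < -tol | inm > 1 + tol))
      stop(sprintf("scalar_map kind '%s' requires values in [0,1]", kind))
    values[grid$mask] <- pmin(pmax(inm, 0), 1)
  }
  if (kind == "gm_volume" && any(inm < -tol))
    stop("gm_volume map must be nonnegative")
  structure(list(grid = grid, values = values, kind = kind, meta = meta),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  inm <- x$values[map_mask(x)]
  cat(sprintf("scalar_map [%s] %dx%dx%d, %d analysed voxels, range [%.4g, %.4g], mean %.4g\n",
              x$kind, x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              length(inm), min(inm), max(inm), mean(inm)))
  invisible(x)
}

#' @export
plot.scalar_map <- function(x, k = NULL, ...) {
  if (is.null(k)) k <- ceiling(x$grid$shape[3] / 2)
  graphics::image(x$values[, , k], asp = x$grid$voxel_size_mm[2] /
                    x$grid$voxel_size_mm[1],
                  main = sprintf("%s (axial slice %d)", x$kind, k), ...)
  invisible(x)
}

# Effective analysis mask of a map: tighter meta$mask if recorded, else the
# grid mask.
map_mask <- function(map) {
  if (!is.null(map$meta$mask)) map$meta$mask else map$grid$mask
}

#' 4D BOLD time series on a grid
#'
#' @param data numeric 4D array (i, j, k, T), T >= 10.
#' @param grid an `image_grid`.
#' @param tr_seconds repetition time in seconds.
#' @param subject_id subject identifier.
#' @return object of class `bold_series`.
#' @export
bold_series <- function(data, grid, tr_seconds, subject_id = "subject") {
  stopifnot(length(dim(data)) == 4L, all(dim(data)[1:3] == grid$shape))
  if (dim(data)[4] < 10L)
    stop("bold_series requires at least 10 time points")
  stopifnot(is.numeric(tr_seconds), tr_seconds > 0)
  inm <- data[array(grid$mask, dim = dim(data))]
  if (any(!is.finite(inm)))
    stop("bold_series: non-finite values inside mask")
  structure(list(grid = grid, data = data, tr_seconds = as.numeric(tr_seconds),
                 subject_id = as.character(subject_id)),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bold_series '%s' %dx%dx%d x %d volumes, TR %.3g s\n",
              x$subject_id, d[1], d[2], d[3], d[4], x$tr_seconds))
  invisible(x)
}
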