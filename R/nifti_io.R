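#' Read a NIfTI volume as a scalar map or BOLD series
#'
#' 3D files come back as a [scalar_map], 4D files as a [bold_series] with the
#' repetition time taken from the header pixdim (seconds), overridable with
#' `tr_seconds`. The grid (shape, voxel sizes, affine) is taken from the
#' header; the mask defaults to all-`TRUE` and can be supplied to tighten it.
#'
#' @param path NIfTI-1/NIfTI-2 file (.nii or .nii.gz).
#' @param kind `kind` tag for 3D maps (see [scalar_map]).
#' @param mask optional logical array on the file's grid.
#' @param tr_seconds optional TR override for 4D files.
#' @param subject_id subject id for 4D files (default: file stem).
#' @return a `scalar_map` (3D) or `bold_series` (4D).
#' @export
read_volume <- function(path, kind = "generic", mask = NULL,
                        tr_seconds = NULL, subject_id = NULL) {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop(sprintf(
                    "failed to read NIfTI '%s': %s", path, conditionMessage(e))))
  dm <- dim(img)
  if (!length(dm) %in% c(3L, 4L))
    stop(sprintf("'%s' is %dD; expected a 3D map or 4D series", path, length(dm)))
  pix <- RNifti::pixdim(img)
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  grid <- image_grid(dm[1:3], voxel_size_mm = abs(pix[1:3]),
                     affine = aff, mask = mask)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dm)
  if (length(dm) == 3L) {
    return(scalar_map(arr, grid, kind = kind, meta = list(source = path)))
  }
  if (dm[4] < 10L)
    stop(sprintf("'%s' has %d time points; a BOLD series needs at least 10",
                 path, dm[4]))
  if (is.null(tr_seconds)) {
    tr_seconds <- if (length(pix) >= 4) pix[4] else NA_real_
    # headers written in msec units
    if (is.finite(tr_seconds) && tr_seconds > 100) tr_seconds <- tr_seconds / 1000
    # pixdim is stored float32; trim read-back noise
    if (is.finite(tr_seconds)) tr_seconds <- signif(tr_seconds, 7)
  }
  if (!is.finite(tr_seconds) || tr_seconds <= 0)
    stop(sprintf("'%s': TR not recoverable from header; pass tr_seconds", path))
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  bold_series(arr, grid, tr_seconds, subject_id)
}

#' Write a scalar map, BOLD series, or mask to NIfTI
#'
#' Data are stored as float32 for maps/series (uint8 for logical masks) with
#' the grid affine and voxel sizes in the header; 4D series carry the TR in
#' pixdim[4] (seconds).
#'
#' @param x a `scalar_map`, `bold_series`, or logical array plus `grid`.
#' @param path output path (.nii or .nii.gz).
#' @param grid required when `x` is a bare array.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, grid = NULL) {
  if (inherits(x, "scalar_map")) {
    arr <- x$values; grid <- x$grid; dt <- "double"
    pd <- c(grid$voxel_size_mm, 0)
  } else if (inherits(x, "bold_series")) {
    arr <- x$data; grid <- x$grid; dt <- "double"
    pd <- c(grid$voxel_size_mm, x$tr_seconds)
  } else {
    if (is.null(grid)) stop("grid required when writing a bare array")
    dt <- if (is.logical(x)) "uint8" else "double"
    arr <- array(if (is.logical(x)) as.integer(x) else as.numeric(x),
                 dim = dim(x))
    pd <- c(grid$voxel_size_mm, 0)
  }
  # pixdim field is qfac followed by 7 dimension scales
  img <- RNifti::asNifti(arr, reference = list(pixdim = c(-1, pd, 0, 0, 0)))
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 4L))
  img <- RNifti::`qform<-`(img, structure(grid$affine, code = 4L))
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}
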