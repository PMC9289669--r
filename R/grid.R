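#' Shared 3D image geometry
#'
#' An `image_grid` bundles the geometry every volume in a cohort must share:
#' array dimensions, voxel sizes in mm, the 4x4 affine mapping (0-based)
#' voxel indices to MNI mm, and the binary analysis mask. All per-subject
#' volumes of one cohort are required to live on an identical grid (shape
#' exactly equal, affine entries within `1e-6`).
#'
#' Voxel indices handed to and returned by R functions are 1-based (the R
#' array convention); reported world coordinates use the NIfTI convention of
#' 0-based indices through the affine, and cluster tables print both.
#'
#' @param shape integer length-3 array dimensions (i, j, k).
#' @param voxel_size_mm positive numeric length-3 voxel edge lengths in mm.
#' @param affine 4x4 numeric matrix, voxel (0-based) to world mm. Default is
#'   a diagonal scaling by the voxel sizes centred on the grid.
#' @param mask logical array of dimension `shape` with at least one `TRUE`
#'   voxel; defaults to all-`TRUE`.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(shape, voxel_size_mm = c(3, 3, 3), affine = NULL,
                       mask = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  voxel_size_mm <- as.numeric(voxel_size_mm)
  stopifnot(length(voxel_size_mm) == 3L, all(voxel_size_mm > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
    # centre the grid on the origin, RAS-ish
    affine[1:3, 4] <- -voxel_size_mm * (shape - 1) / 2
  }
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (is.null(mask)) mask <- array(TRUE, dim = shape)
  if (is.double(mask) || is.integer(mask)) mask <- array(mask != 0, dim = shape)
  stopifnot(is.logical(mask), all(dim(mask) == shape))
  if (!any(mask)) stop("mask must contain at least one TRUE voxel")
  structure(list(shape = shape, voxel_size_mm = voxel_size_mm,
                 affine = affine, mask = mask),
            class = "image_grid")
}

#' Test whether two grids are compatible for one cohort
#'
#' Shapes must be exactly equal; affine entries and voxel sizes must agree
#' within `tol` (NIfTI headers store floats).
#'
#' @param a,b `image_grid` objects.
#' @param tol numeric tolerance on affine entries and voxel sizes.
#' @param check_mask also require identical masks.
#' @return logical scalar.
#' @export
grids_equal <- function(a, b, tol = 1e-6, check_mask = FALSE) {
  ok <- all(a$shape == b$shape) &&
    all(abs(a$voxel_size_mm - b$voxel_size_mm) <= tol) &&
    all(abs(a$affine - b$affine) <= tol)
  if (ok && check_mask) ok <- identical(a$mask, b$mask)
  ok
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid %dx%dx%d, voxels %.3gx%.3gx%.3g mm, %d in-mask voxels\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3],
              sum(x$mask)))
  invisible(x)
}

#' Convert 1-based voxel indices to world (MNI) mm coordinates
#'
#' @param ijk integer matrix (n x 3) or length-3 vector of 1-based indices.
#' @param grid an `image_grid`.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(ijk, grid) {
  if (is.null(dim(ijk))) ijk <- matrix(ijk, nrow = 1)
  h <- cbind(ijk - 1, 1)   # affine is defined on 0-based indices
  xyz <- h %*% t(grid$affine)
  xyz[, 1:3, drop = FALSE]
}

# Integer offsets for a connectivity scheme: 6 (faces), 18 (faces+edges),
# 26 (full 3x3x3 shell). Never includes the zero offset.
connectivity_offsets <- function(connectivity = 26) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be one of 6, 18, 26")
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  nz <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6"  = nz == 1,
                 "18" = nz >= 1 & nz <= 2,
                 "26" = nz >= 1)
  unname(off[keep, , drop = FALSE])
}

#' In-mask neighbors of a voxel
#'
#' Returns the in-bounds, in-mask neighbor indices of `index` under the given
#' connectivity (6 = faces, 18 = faces + edges, 26 = the full 26-voxel
#' shell used by regional homogeneity). The centre voxel is never included.
#'
#' @param index length-3 integer, 1-based voxel index.
#' @param grid an `image_grid`.
#' @param connectivity 6, 18 or 26.
#' @return integer matrix (m x 3) of neighbor indices (possibly 0 rows).
#' @export
neighborhood <- function(index, grid, connectivity = 26) {
  index <- as.integer(index)
  stopifnot(length(index) == 3L, all(index >= 1L), all(index <= grid$shape))
  off <- connectivity_offsets(connectivity)
  nb <- sweep(off, 2, index, "+")
  inb <- nb[, 1] >= 1 & nb[, 1] <= grid$shape[1] &
         nb[, 2] >= 1 & nb[, 2] <= grid$shape[2] &
         nb[, 3] >= 1 & nb[, 3] <= grid$shape[3]
  nb <- nb[inb, , drop = FALSE]
  if (nrow(nb) == 0) return(nb)
  keep <- grid$mask[nb]
  nb[keep, , drop = FALSE]
}

# Linear (column-major, 1-based) index from voxel triples.
ijk_to_linear <- function(ijk, shape) {
  (ijk[, 1]) + (ijk[, 2] - 1L) * shape[1] + (ijk[, 3] - 1L) * shape[1] * shape[2]
}

#' Label connected components of a binary volume
#'
#' Connected-component labelling under 6/18/26 connectivity, restricted to
#' `TRUE` voxels. Labels are assigned in decreasing cluster size (label 1 is
#' the largest cluster); ties are ordered by the smallest member linear index
#' so the labelling does not depend on scan order.
#'
#' @param binary logical array on `grid$shape`.
#' @param grid an `image_grid` (used for shape and voxel volume).
#' @param connectivity 6, 18 or 26 (default 26, the usual alphasim setting).
#' @return list with `labels` (integer array, 0 = background) and `table`
#'   (data.frame: cluster_id, n_voxels, size_mm3).
#' @export
label_clusters <- function(binary, grid, connectivity = 26) {
  stopifnot(all(dim(binary) == grid$shape))
  vox <- which(binary, arr.ind = TRUE)
  labels <- array(0L, dim = grid$shape)
  vol_mm3 <- prod(grid$voxel_size_mm)
  if (nrow(vox) == 0) {
    return(list(labels = labels,
                table = data.frame(cluster_id = integer(), n_voxels = integer(),
                                   size_mm3 = numeric())))
  }
  lin <- ijk_to_linear(vox, grid$shape)
  idx_of <- integer(0)
  comp <- cluster_membership(vox, lin, grid$shape, connectivity)
  # order components: largest first, ties by smallest member linear index
  sizes <- tabulate(comp)
  minlin <- vapply(split(lin, comp), min, numeric(1))
  ord <- order(-sizes, minlin)
  relab <- integer(length(sizes))
  relab[ord] <- seq_along(ord)
  comp <- relab[comp]
  labels[lin] <- comp
  sizes <- tabulate(comp)
  list(labels = labels,
       table = data.frame(cluster_id = seq_along(sizes),
                          n_voxels = as.integer(sizes),
                          size_mm3 = sizes * vol_mm3))
}

# Component id per voxel (rows of vox) via an igraph over neighbor pairs.
cluster_membership <- function(vox, lin, shape, connectivity) {
  n <- nrow(vox)
  if (n == 1L) return(1L)
  off <- connectivity_offsets(connectivity)
  # half the offsets suffice for undirected edges
  off <- off[ijk_to_linear(off + 2L, c(3L, 3L, 3L)) > 14L, , drop = FALSE]
  ei <- integer(0); ej <- integer(0)
  for (r in seq_len(nrow(off))) {
    nb <- sweep(vox, 2, off[r, ], "+")
    inb <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
           nb[, 2] >= 1 & nb[, 2] <= shape[2] &
           nb[, 3] >= 1 & nb[, 3] <= shape[3]
    if (!any(inb)) next
    m <- match(ijk_to_linear(nb[inb, , drop = FALSE], shape), lin)
    hit <- !is.na(m)
    if (!any(hit)) next
    ei <- c(ei, which(inb)[hit])
    ej <- c(ej, m[hit])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(ei)) g <- igraph::add_edges(g, rbind(ei, ej))
  as.integer(igraph::components(g)$membership)
}

# Sparse in-mask adjacency (V x V, including self-loops on the diagonal)
# over the in-mask voxels, in the order given by which(mask). Used by the
# ReHo engine to accumulate neighborhood rank sums in one sparse product.
mask_adjacency <- function(grid, connectivity = 26, include_self = TRUE) {
  mask <- grid$mask
  vox <- which(mask, arr.ind = TRUE)
  lin <- ijk_to_linear(vox, grid$shape)
  n <- nrow(vox)
  off <- connectivity_offsets(connectivity)
  off <- off[ijk_to_linear(off + 2L, c(3L, 3L, 3L)) > 14L, , drop = FALSE]
  ei <- vector("list", nrow(off)); ej <- vector("list", nrow(off))
  for (r in seq_len(nrow(off))) {
    nb <- sweep(vox, 2, off[r, ], "+")
    inb <- nb[, 1] >= 1 & nb[, 1] <= grid$shape[1] &
           nb[, 2] >= 1 & nb[, 2] <= grid$shape[2] &
           nb[, 3] >= 1 & nb[, 3] <= grid$shape[3]
    m <- match(ijk_to_linear(nb[inb, , drop = FALSE], grid$shape), lin)
    hit <- !is.na(m)
    ei[[r]] <- which(inb)[hit]
    ej[[r]] <- m[hit]
  }
  i <- unlist(ei); j <- unlist(ej)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n))
  if (include_self) A <- A + Matrix::Diagonal(n)
  A
}
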