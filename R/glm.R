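#' Voxelwise two-sample GLM contrast with nuisance covariates
#'
#' At every in-mask voxel fits, by least squares,
#' `value ~ intercept + group + age + sex`, with the group indicator coded 0
#' for `group_a` and 1 for `group_b` (so positive t means `group_b` >
#' `group_a`), age mean-centred, and sex coded 0 = female / 1 = male. The
#' group t statistic is `beta_group / SE(beta_group)` and the two-tailed p
#' comes from Student's t with `df = N - rank(design)` (N - 4 for the full
#' design). Voxels with zero residual variance (e.g. identical groups
#' relabelled) get t = 0 and p = 1.
#'
#' @param maps list of `coupling_z` `scalar_map`s, one per subject, in the
#'   order of `subjects` rows.
#' @param subjects data.frame with columns `subject_id`, `group`,
#'   `age_years`, `sex` (rows aligned with `maps`).
#' @param group_a,group_b group labels to contrast.
#' @param covariates character subset of `c("age", "sex")` (default both).
#' @param mask optional analysis mask; defaults to the intersection of the
#'   selected subjects' coupling masks.
#' @param keep_residuals store standardized residual maps (needed by
#'   [estimate_smoothness]).
#' @return object of class `glm_result`: `t_map`, `p_map` (two-tailed),
#'   `df`, `contrast`, `n_per_group`, `mask`, and optionally `residuals`
#'   (a V x N matrix over in-mask voxels).
#' @export
glm_contrast <- function(maps, subjects, group_a, group_b,
                         covariates = c("age", "sex"), mask = NULL,
                         keep_residuals = TRUE) {
  sel <- subjects$group %in% c(group_a, group_b)
  if (!any(subjects$group == group_a) || !any(subjects$group == group_b))
    stop("both contrast groups must be present")
  subjects <- subjects[sel, , drop = FALSE]
  maps <- maps[sel]
  n <- nrow(subjects)
  grid <- maps[[1]]$grid
  for (m in maps) if (!grids_equal(grid, m$grid))
    stop("glm_contrast: subject maps on different grids")
  if (is.null(mask)) mask <- intersection_mask(maps)
  g_ind <- as.numeric(subjects$group == group_b)
  X <- cbind(intercept = 1, group = g_ind)
  if ("age" %in% covariates) {
    age <- subjects$age_years
    if (any(is.na(age))) stop("glm_contrast: missing age covariate")
    X <- cbind(X, age = age - mean(age))
  }
  if ("sex" %in% covariates) {
    sx <- as.numeric(subjects$sex == "male")
    if (any(is.na(sx))) stop("glm_contrast: missing sex covariate")
    X <- cbind(X, sex = sx)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    stop(sprintf("glm_contrast: rank-deficient design; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  v <- sum(mask)
  Y <- vapply(maps, function(m) m$values[mask], numeric(v))  # V x N
  df <- n - qrX$rank
  if (df < 1) stop("glm_contrast: no residual degrees of freedom")
  xtx_inv <- solve(crossprod(X))
  beta <- t(qr.coef(qrX, t(Y)))                 # V x p
  res <- t(Y) - X %*% t(beta)                   # N x V
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 * xtx_inv[2, 2])
  tt <- ifelse(se > 0, beta[, 2] / se, 0)
  pp <- ifelse(se > 0, 2 * stats::pt(-abs(tt), df), 1)
  t_arr <- array(0, dim = grid$shape); t_arr[mask] <- tt
  p_arr <- array(1, dim = grid$shape); p_arr[!grid$mask] <- 0
  p_arr[mask] <- pp
  out <- list(
    t_map = scalar_map(t_arr, grid, "tstat", meta = list(mask = mask)),
    p_map = scalar_map(pmin(pmax(p_arr, 0), 1), grid, "pvalue",
                       meta = list(mask = mask)),
    df = df,
    contrast = sprintf("%s > %s", group_b, group_a),
    n_per_group = c(sum(g_ind == 0), sum(g_ind == 1)),
    mask = mask, grid = grid)
  if (keep_residuals) {
    sd_res <- sqrt(sigma2)
    sd_res[sd_res == 0] <- 1
    out$residuals <- t(res) / sd_res            # V x N, standardized
  }
  class(out) <- "glm_result"
  out
}

#' @export
print.glm_result <- function(x, ...) {
  tt <- x$t_map$values[x$mask]
  cat(sprintf("glm_result: %s (n = %d vs %d, df = %d)\n", x$contrast,
              x$n_per_group[1], x$n_per_group[2], x$df))
  cat(sprintf("  %d voxels, t range [%.2f, %.2f], %d voxels with p < 0.001\n",
              length(tt), min(tt), max(tt),
              sum(x$p_map$values[x$mask] < 0.001)))
  invisible(x)
}

#' Benjamini-Hochberg FDR correction over a p-value map
#'
#' Step-up procedure over the in-mask voxels: with ordered p-values p(1) <=
#' ... <= p(m), rejects all voxels with p <= p(i*) where i* is the largest i
#' with p(i) <= (i/m) q.
#'
#' @param p_map `scalar_map` of kind `"pvalue"` (or a bare numeric vector).
#' @param q FDR level in (0, 1).
#' @param mask optional mask overriding the map's analysis mask.
#' @return list: `significant` (logical array, or vector for vector input),
#'   `p_threshold` (largest rejected raw p, `NA` if none), `n_rejected`,
#'   `m` (number of tests).
#' @export
fdr_correct <- function(p_map, q, mask = NULL) {
  stopifnot(q > 0, q < 1)
  if (is.numeric(p_map) && is.null(dim(p_map))) {
    p <- p_map
    adj <- stats::p.adjust(p, method = "BH")
    rej <- adj <= q
    return(list(significant = rej,
                p_threshold = if (any(rej)) max(p[rej]) else NA_real_,
                n_rejected = sum(rej), m = length(p)))
  }
  if (is.null(mask)) mask <- map_mask(p_map)
  p <- p_map$values[mask]
  adj <- stats::p.adjust(p, method = "BH")
  rej <- adj <= q
  sig <- array(FALSE, dim = p_map$grid$shape)
  sig[mask] <- rej
  list(significant = sig,
       p_threshold = if (any(rej)) max(p[rej]) else NA_real_,
       n_rejected = sum(rej), m = length(p))
}
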