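#' End-to-end run configuration
#'
#' A single configuration (optionally loaded from YAML via
#' [read_run_config]) drives the full analysis: simulate (or load) a
#' cohort, compute per-subject ReHo and coupling maps, run the default
#' group contrasts, the dose correlation, and the RE classifier. The
#' default contrast list mirrors the analysis design the package targets:
#' pre-RT vs post-RT-RE-negative at FDR q = 0.05, pre-RT vs
#' post-RT-RE-positive at FDR q = 0.01, and RE-negative vs RE-positive with
#' Monte-Carlo cluster correction (voxel p < 0.001, cluster alpha 0.01).
#' One global seed fans out to fixed per-stage seeds so a single number
#' reproduces the whole run.
#'
#' @param out_dir output directory.
#' @param cohort_dir optional directory of an existing cohort (from
#'   [write_cohort]); when `NULL` a cohort is simulated from
#'   `cohort_config`.
#' @param cohort_config a [cohort_config] for simulation.
#' @param reho_params,coupling_params analysis parameters.
#' @param contrasts list of `list(a, b, correction, q | voxel_p +
#'   cluster_alpha)` entries.
#' @param alphasim_iter Monte-Carlo iterations for alphasim contrasts.
#' @param cv_config a [cv_config] for the classifier stage.
#' @param run_permutation run the label-permutation test (slow; off by
#'   default).
#' @param seed global seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, cohort_dir = NULL,
                       cohort_config = sfcouple::cohort_config(),
                       reho_params = sfcouple::reho_params(),
                       coupling_params = sfcouple::coupling_params(),
                       contrasts = NULL, alphasim_iter = 1000,
                       cv_config = sfcouple::cv_config(),
                       run_permutation = FALSE, seed = 1L) {
  if (is.null(contrasts)) {
    contrasts <- list(
      list(a = "pre_rt", b = "post_rt_re_neg", correction = "fdr", q = 0.05),
      list(a = "pre_rt", b = "post_rt_re_pos", correction = "fdr", q = 0.01),
      list(a = "post_rt_re_neg", b = "post_rt_re_pos",
           correction = "alphasim", voxel_p = 0.001, cluster_alpha = 0.01))
  }
  for (ct in contrasts) if (identical(ct$a, ct$b))
    stop("run_config: contrast groups must be distinct")
  if (!is.null(cohort_dir) && !file.exists(file.path(cohort_dir, "manifest.json")))
    stop(sprintf("run_config: cohort_dir '%s' has no manifest.json", cohort_dir))
  structure(list(out_dir = out_dir, cohort_dir = cohort_dir,
                 cohort_config = cohort_config, reho_params = reho_params,
                 coupling_params = coupling_params, contrasts = contrasts,
                 alphasim_iter = alphasim_iter, cv_config = cv_config,
                 run_permutation = run_permutation, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Recognized top-level keys: `out_dir`, `cohort_dir`, `seed`,
#' `alphasim_iter`, `run_permutation`, plus nested `reho`, `coupling`,
#' `cv`, `cohort` parameter blocks and a `contrasts` list; anything omitted
#' falls back to the package defaults.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(out_dir = y$out_dir %||% "sfcouple_out",
               cohort_dir = y$cohort_dir,
               seed = y$seed %||% 1L,
               alphasim_iter = y$alphasim_iter %||% 1000,
               run_permutation = isTRUE(y$run_permutation))
  if (!is.null(y$reho)) args$reho_params <- do.call(reho_params, y$reho)
  if (!is.null(y$coupling)) args$coupling_params <- do.call(coupling_params, y$coupling)
  if (!is.null(y$cv)) args$cv_config <- do.call(cv_config, y$cv)
  if (!is.null(y$cohort)) args$cohort_config <- do.call(cohort_config, y$cohort)
  if (!is.null(y$contrasts)) args$contrasts <- y$contrasts
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Stages: simulate/load -> ReHo + coupling -> group statistics (contrasts,
#' smoothness, alphasim where requested, dose correlation) -> classifier.
#' Every stage writes its outputs under `config$out_dir` and the manifest
#' records parameters, per-stage seeds, and md5 hashes of every written
#' file; with the same config and seed the manifest hashes are identical
#' across runs.
#'
#' @param config a [run_config].
#' @return the manifest (list), invisibly written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(path) { written <<- c(written, path); path }
  manifest <- list(seed = config$seed, stages = list())

  # --- stage: cohort -------------------------------------------------------
  if (is.null(config$cohort_dir)) {
    cohort <- generate_cohort(config$cohort_config, seed = config$seed)
    cdir <- file.path(config$out_dir, "cohort")
    write_cohort(cohort, cdir)
    written <- c(written, list.files(cdir, full.names = TRUE))
  } else {
    cohort <- read_cohort(config$cohort_dir)
  }
  subjects <- cohort$subjects
  manifest$stages$cohort <- list(n_subjects = nrow(subjects),
                                 seed = config$seed)

  # --- stage: coupling maps ------------------------------------------------
  cm <- cohort_coupling_maps(cohort, config$reho_params, config$coupling_params)
  write_volume(cm$mask, emit(file.path(config$out_dir, "coupling_mask.nii.gz")),
               grid = cohort$grid)
  manifest$stages$coupling <- list(n_mask_voxels = sum(cm$mask))

  # --- stage: group statistics --------------------------------------------
  stats_out <- list()
  for (ci in seq_along(config$contrasts)) {
    ct <- config$contrasts[[ci]]
    gl <- glm_contrast(cm$maps, subjects, ct$a, ct$b, mask = cm$mask)
    tag <- sprintf("contrast_%s_vs_%s", ct$a, ct$b)
    write_volume(gl$t_map, emit(file.path(config$out_dir,
                                          paste0(tag, "_t.nii.gz"))))
    write_volume(gl$p_map, emit(file.path(config$out_dir,
                                          paste0(tag, "_p.nii.gz"))))
    if (identical(ct$correction, "alphasim")) {
      fw <- estimate_smoothness(gl)
      as_res <- alphasim_threshold(
        image_grid(cohort$grid$shape, cohort$grid$voxel_size_mm,
                   cohort$grid$affine, cm$mask),
        fw, voxel_p = ct$voxel_p, cluster_alpha = ct$cluster_alpha,
        n_iter = config$alphasim_iter, seed = config$seed + 100L + ci)
      jsonlite::write_json(
        as_res[c("est_fwhm_mm", "n_iterations", "voxel_p", "cluster_alpha",
                 "k_threshold_voxels")],
        emit(file.path(config$out_dir, paste0(tag, "_alphasim.json"))),
        auto_unbox = TRUE, digits = NA)
      rep_ <- apply_cluster_correction(gl, as_res)
      stats_out[[tag]] <- list(correction = "alphasim",
                               k_threshold = as_res$k_threshold_voxels,
                               n_clusters = nrow(rep_))
    } else {
      fdr <- fdr_correct(gl$p_map, q = ct$q, mask = cm$mask)
      rep_ <- fdr_cluster_report(gl, fdr)
      stats_out[[tag]] <- list(correction = "fdr", q = ct$q,
                               n_rejected = fdr$n_rejected,
                               n_clusters = nrow(rep_))
    }
    utils::write.table(rep_, emit(file.path(config$out_dir,
                                            paste0(tag, "_clusters.tsv"))),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  # dose correlation over the pooled post-RT subjects
  post <- subjects$group %in% c("post_rt_re_neg", "post_rt_re_pos")
  for (h in c("left", "right")) {
    dc <- tryCatch(
      dose_correlation(cm$maps[post], subjects[post, , drop = FALSE], h,
                       cohort$temporal_masks[[h]] & cm$mask, q = 0.05),
      error = function(e) NULL)
    if (is.null(dc)) next
    tag <- paste0("dose_", h)
    write_volume(dc$r_map, emit(file.path(config$out_dir,
                                          paste0(tag, "_r.nii.gz"))))
    stats_out[[tag]] <- list(n_subjects = dc$n_subjects,
                             n_significant = sum(dc$significant))
  }
  manifest$stages$group_stats <- stats_out

  # --- stage: classifier ---------------------------------------------------
  cls <- subjects$group %in% c("post_rt_re_neg", "post_rt_re_pos")
  feats <- extract_features(cm$maps[cls], cm$mask)
  labs <- factor(subjects$group[cls],
                 levels = c("post_rt_re_neg", "post_rt_re_pos"))
  cvc <- config$cv_config
  cvc$seed <- config$seed + 500L
  report <- nested_cv(feats, labs, cvc)
  if (config$run_permutation) {
    pt <- permutation_test(feats, labs, cvc,
                           observed_metric = report$metrics$accuracy)
    report$permutation_null <- pt$null
    report$permutation_p <- pt$p
  }
  wb <- weight_backprojection(report, feats, cohort$grid)
  write_volume(wb$weight_map, emit(file.path(config$out_dir,
                                             "svm_weight.nii.gz")))
  write_volume(wb$selection_frequency,
               emit(file.path(config$out_dir, "svm_selection_freq.nii.gz")))
  utils::write.table(report$pooled,
                     emit(file.path(config$out_dir, "svm_predictions.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest$stages$classifier <- c(report$metrics[c("accuracy", "sensitivity",
                                                   "specificity", "auc")],
                                  list(permutation_p = report$permutation_p))

  manifest$parameters <- list(
    reho = unclass(config$reho_params),
    coupling = unclass(config$coupling_params),
    contrasts = config$contrasts,
    cv = unclass(config$cv_config)[c("k_outer", "k_inner", "mask_p",
                                     "lasso_grid", "svm_c_grid")])
  manifest$files <- as.list(tools::md5sum(sort(unique(written))))
  names(manifest$files) <- basename(sort(unique(written)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}
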