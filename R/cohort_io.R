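#' Write a synthetic cohort to disk
#'
#' Lays out NIfTI volumes (`bold_<id>.nii.gz`, `gm_<id>.nii.gz`, the analysis
#' mask and per-hemisphere temporal masks), the subject metadata CSV
#' (columns: subject_id, group, age_years, sex, mdrt_left_gy, mdrt_right_gy,
#' rt_to_scan_months), the ground-truth sidecar `truth.json`, and a
#' `manifest.json` listing every file plus the generator seed.
#'
#' @param cohort a `synthetic_cohort`.
#' @param directory output directory (created if absent).
#' @return path to the manifest, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (s in seq_along(cohort$bold)) {
    id <- cohort$subjects$subject_id[s]
    pb <- file.path(directory, sprintf("bold_%s.nii.gz", id))
    pg <- file.path(directory, sprintf("gm_%s.nii.gz", id))
    write_volume(cohort$bold[[s]], pb)
    write_volume(cohort$gm[[s]], pg)
    paths[[paste0("bold_", id)]] <- basename(pb)
    paths[[paste0("gm_", id)]] <- basename(pg)
  }
  write_volume(cohort$grid$mask, file.path(directory, "mask.nii.gz"),
               grid = cohort$grid)
  write_volume(cohort$temporal_masks$left,
               file.path(directory, "temporal_left.nii.gz"), grid = cohort$grid)
  write_volume(cohort$temporal_masks$right,
               file.path(directory, "temporal_right.nii.gz"), grid = cohort$grid)
  meta_cols <- c("subject_id", "group", "age_years", "sex", "mdrt_left_gy",
                 "mdrt_right_gy", "rt_to_scan_months")
  utils::write.csv(cohort$subjects[, meta_cols],
                   file.path(directory, "metadata.csv"), row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(directory, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(seed = cohort$seed,
                   grid_shape = cohort$grid$shape,
                   voxel_size_mm = cohort$grid$voxel_size_mm,
                   tr_seconds = cohort$config$tr_seconds,
                   n_subjects = nrow(cohort$subjects),
                   files = c(paths,
                             list(mask = "mask.nii.gz",
                                  temporal_left = "temporal_left.nii.gz",
                                  temporal_right = "temporal_right.nii.gz",
                                  metadata = "metadata.csv",
                                  truth = "truth.json")))
  mp <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read a cohort written by [write_cohort]
#'
#' Every volume is checked against the cohort grid (shape exactly, affine
#' within 1e-6); a mismatching file is rejected.
#'
#' @param directory cohort directory containing `manifest.json`.
#' @return list with `subjects`, `bold`, `gm`, `grid`, `temporal_masks`,
#'   `truth`, `seed` (class `synthetic_cohort` minus the config).
#' @export
read_cohort <- function(directory) {
  manifest <- jsonlite::read_json(file.path(directory, "manifest.json"),
                                  simplifyVector = TRUE)
  fp <- function(x) file.path(directory, x)
  subjects <- utils::read.csv(fp(manifest$files$metadata),
                              stringsAsFactors = FALSE)
  mask_map <- read_volume(fp(manifest$files$mask))
  grid <- image_grid(mask_map$grid$shape, mask_map$grid$voxel_size_mm,
                     mask_map$grid$affine, mask = mask_map$values != 0)
  check_grid <- function(obj, path) {
    if (!grids_equal(grid, obj$grid))
      stop(sprintf("'%s' is not on the cohort grid", path))
    obj
  }
  bold <- vector("list", nrow(subjects))
  gm <- vector("list", nrow(subjects))
  for (s in seq_len(nrow(subjects))) {
    id <- subjects$subject_id[s]
    pb <- fp(manifest$files[[paste0("bold_", id)]])
    pg <- fp(manifest$files[[paste0("gm_", id)]])
    b <- check_grid(read_volume(pb, tr_seconds = manifest$tr_seconds,
                                subject_id = id), pb)
    bold[[s]] <- bold_series(b$data, grid, b$tr_seconds, id)
    g3 <- check_grid(read_volume(pg, kind = "generic"), pg)
    gm[[s]] <- scalar_map(g3$values, grid, "gm_volume",
                          meta = list(subject_id = id))
  }
  tml <- check_grid(read_volume(fp(manifest$files$temporal_left)),
                    "temporal_left")
  tmr <- check_grid(read_volume(fp(manifest$files$temporal_right)),
                    "temporal_right")
  truth <- jsonlite::read_json(file.path(directory, "truth.json"),
                               simplifyVector = FALSE)
  truth$effect_clusters <- lapply(truth$effect_clusters, function(e)
    list(name = e$name, effects = lapply(e$effects, as.numeric),
         voxels = as.integer(unlist(e$voxels)), sign = e$sign))
  truth$dose_regions <- lapply(truth$dose_regions, function(e)
    list(hemisphere = e$hemisphere, voxels = as.integer(unlist(e$voxels))))
  structure(list(subjects = subjects, bold = bold, gm = gm, grid = grid,
                 temporal_masks = list(left = tml$values != 0,
                                       right = tmr$values != 0),
                 truth = truth, seed = manifest$seed),
            class = "synthetic_cohort")
}

#' Compute every subject's smoothed coupling-z map for a cohort
#'
#' Runs [subject_coupling_pipeline] per subject and returns the maps plus
#' the cohort-wide intersection coupling mask used by the group analyses.
#'
#' @param cohort a `synthetic_cohort` (or any list with `bold`, `gm`,
#'   `grid`).
#' @param reho_params,coupling_params analysis parameters.
#' @return list: `maps` (per subject), `mask` (intersection logical array).
#' @export
cohort_coupling_maps <- function(cohort,
                                 reho_params = sfcouple::reho_params(),
                                 coupling_params = sfcouple::coupling_params()) {
  maps <- lapply(seq_along(cohort$bold), function(s)
    subject_coupling_pipeline(cohort$bold[[s]], cohort$gm[[s]],
                              reho_params = reho_params,
                              coupling_params = coupling_params))
  list(maps = maps, mask = intersection_mask(maps))
}
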