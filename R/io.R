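#' Read a CT volume from NIfTI
#'
#' Reads a NIfTI file and returns a [voxel_volume] with spacing (mm) taken
#' from the header `pixdim`. A missing or non-positive spacing is a
#' metadata error.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return A [voxel_volume].
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  sp <- RNifti::pixdim(img)[seq_along(d)]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("metadata error: missing or non-positive voxel spacing in ", path,
         call. = FALSE)
  voxel_volume(array(as.numeric(img), dim = d), spacing = sp)
}

#' Read a binary mask from NIfTI
#'
#' As [read_volume()], but validates that every voxel is exactly 0 or 1;
#' stray labels are reported, not thresholded away.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return A logical array with attribute `spacing` (mm).
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  sp <- RNifti::pixdim(img)[seq_along(d)]
  m <- as_binary_mask(array(as.numeric(img), dim = d))
  attr(m, "spacing") <- sp
  m
}

#' Write a volume or mask to NIfTI
#'
#' @param x a [voxel_volume], or a logical/0-1 array (written as integers).
#' @param path output path (`.nii.gz` recommended).
#' @param spacing voxel spacing in mm; taken from `x` when it is a
#'   [voxel_volume].
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, spacing = NULL) {
  if (inherits(x, "voxel_volume")) {
    data <- x$data
    spacing <- x$spacing
  } else {
    data <- if (is.logical(x)) array(as.integer(x), dim = dim(x)) else x
    if (is.null(spacing)) spacing <- attr(x, "spacing")
    if (is.null(spacing)) stop("spacing required to write a bare array",
                               call. = FALSE)
  }
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- as.numeric(spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a cohort table to CSV
#'
#' Plain CSV with a stable column order; factors are written as labels.
#'
#' @param table cohort `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Restores the factor codings used throughout the statistics pipeline
#' (glucose group levels and reference categories) and the ordinal trend
#' coding if absent.
#'
#' @param path CSV path written by [write_cohort()] or following its column
#'   dictionary.
#' @return A cohort `data.frame`.
#' @export
read_cohort <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if ("glucose_group" %in% names(d)) {
    d$glucose_group <- factor(d$glucose_group, levels = GROUP_LEVELS)
    if (!"group_ordinal" %in% names(d))
      d$group_ordinal <- GROUP_ORDINAL[as.character(d$glucose_group)]
  }
  refs <- list(sex = c("male", "female"), smoking = c("never", "current"),
               physical_activity = c("no", "yes"),
               education = c("high_school", "elementary", "university"),
               alcohol = c("moderate", "low", "low_moderate",
                           "moderate_high", "high"),
               season = c("fall", "winter", "spring", "summer"),
               lipid_med = c("no", "yes"))
  for (v in names(refs))
    if (v %in% names(d)) d[[v]] <- factor(d[[v]], levels = refs[[v]])
  d
}

#' Load and validate a pipeline run configuration
#'
#' Reads a YAML configuration (or accepts an equivalent list) and validates
#' every numeric parameter against its type invariants at load time: the
#' fat window, QC distances, cut-off and seed are checked before any stage
#' runs.
#'
#' @param config path to a YAML file, or a list.
#' @return A validated `run_config` list with elements `seed`, `out_dir`,
#'   `fat_window`, `qc`, `phantom_noise_sd_hu`, `stages`.
#' @export
load_run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(cfg))
  if (is.null(cfg$seed)) stop("config requires a seed", call. = FALSE)
  seed <- as.integer(cfg$seed)
  fw <- do.call(fat_window, as.list(cfg$fat_window %||%
                                      list(lo_hu = -190, hi_hu = -30)))
  qc <- do.call(qc_params, as.list(cfg$qc %||% list()))
  noise <- cfg$phantom_noise_sd_hu %||% 10
  if (noise < 0) stop("phantom_noise_sd_hu must be >= 0", call. = FALSE)
  stages <- cfg$stages %||% c("phantom", "quantify", "qc", "abdominal",
                              "cohort", "stats")
  structure(list(seed = seed, out_dir = cfg$out_dir %||% ".",
                 fat_window = fw, qc = qc, phantom_noise_sd_hu = noise,
                 stages = stages),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic pipeline
#'
#' Executes the requested stages in order - cardiac phantom generation, EAT
#' quantification, segmentation QC, abdominal quantification, cohort
#' synthesis and the statistical battery - writing every artifact under
#' `out_dir` together with a machine-readable JSON manifest (seed, package
#' version, per-stage outputs). Any stage error aborts with the manifest
#' recording the failed stage.
#'
#' @param config a `run_config` from [load_run_config()], a list, or a YAML
#'   path.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else
    load_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("epifat")),
                   stages = list())
  outfile <- file.path(cfg$out_dir, "manifest.json")
  phantom <- NULL; abphantom <- NULL; cohort <- NULL
  for (stage in cfg$stages) {
    res <- tryCatch({
      out <- switch(stage,
        phantom = {
          phantom <- generate_cardiac_phantom(noise_sd_hu =
            cfg$phantom_noise_sd_hu, seed = cfg$seed)
          vpath <- file.path(cfg$out_dir, "cardiac_volume.nii.gz")
          write_volume(phantom$volume, vpath)
          ppath <- file.path(cfg$out_dir, "pericardium.nii.gz")
          write_volume(phantom$truth$pericardium_mask, ppath,
                       phantom$volume$spacing)
          cpath <- file.path(cfg$out_dir, "chambers.nii.gz")
          write_volume(phantom$truth$chamber_mask, cpath,
                       phantom$volume$spacing)
          tpath <- file.path(cfg$out_dir, "cardiac_truth.json")
          jsonlite::write_json(phantom$truth[c("true_eatv_ml",
            "true_eata_hu", "fat_center_hu", "noise_sd_hu")], tpath,
            auto_unbox = TRUE, digits = NA)
          c(vpath, ppath, cpath, tpath)
        },
        quantify = {
          meas <- quantify_eat(phantom$volume,
                               phantom$truth$pericardium_mask,
                               phantom$truth$chamber_mask, cfg$fat_window)
          mpath <- file.path(cfg$out_dir, "eat_measurement.json")
          jsonlite::write_json(unclass(meas), mpath, auto_unbox = TRUE,
                               digits = NA)
          cpath <- file.path(cfg$out_dir, "eat_measurement.csv")
          write.csv(fat_measurement_row(meas, "phantom"), cpath,
                    row.names = FALSE)
          c(mpath, cpath)
        },
        qc = {
          rep_ <- qc_check(phantom$truth$pericardium_mask,
                           phantom$truth$pericardium_mask,
                           phantom$volume$spacing, cfg$qc)
          qpath <- file.path(cfg$out_dir, "qc_report.json")
          jsonlite::write_json(unclass(rep_), qpath, auto_unbox = TRUE,
                               digits = NA)
          qpath
        },
        abdominal = {
          abphantom <- generate_abdominal_phantom(seed = cfg$seed)
          spath <- file.path(cfg$out_dir, "abdominal_slice.nii.gz")
          write_volume(abphantom$slice, spath)
          meas <- quantify_abdominal(abphantom$slice, cfg$fat_window,
                                     abphantom$truth$lean_wall_mask)
          apath <- file.path(cfg$out_dir, "abdominal_measurement.json")
          jsonlite::write_json(unclass(meas)[c("vat_area_cm2",
            "sat_area_cm2", "vat_median_hu", "sat_median_hu")], apath,
            auto_unbox = TRUE, digits = NA)
          c(spath, apath)
        },
        cohort = {
          cohort <- generate_cohort(seed = cfg$seed)
          cpath <- file.path(cfg$out_dir, "cohort.csv")
          write_cohort(cohort, cpath)
          cpath
        },
        stats = {
          if (is.null(cohort)) cohort <- generate_cohort(seed = cfg$seed)
          summ <- summarize_groups(cohort)
          spath <- file.path(cfg$out_dir, "group_summary.csv")
          write.csv(summ$continuous, spath, row.names = FALSE)
          conf <- qualify_confounders(cohort)
          fits <- fit_staged_models(cohort, "eatv", "groups",
                                    confounders = attr(conf, "qualified"))
          fpath <- file.path(cfg$out_dir, "eatv_models.csv")
          write.csv(model_forest_table(fits), fpath, row.names = FALSE)
          jpath <- file.path(cfg$out_dir, "pairwise_regressions.csv")
          write.csv(pairwise_regressions(cohort), jpath, row.names = FALSE)
          c(spath, fpath, jpath)
        },
        stop("unknown stage: ", stage, call. = FALSE))
      list(status = "ok", outputs = as.list(out))
    }, error = function(e) list(status = "error",
                                message = conditionMessage(e)))
    manifest$stages[[stage]] <- res
    if (identical(res$status, "error")) {
      manifest$failed_stage <- stage
      jsonlite::write_json(manifest, outfile, auto_unbox = TRUE, digits = NA)
      stop("pipeline stage '", stage, "' failed: ", res$message,
           call. = FALSE)
    }
  }
  jsonlite::write_json(manifest, outfile, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
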