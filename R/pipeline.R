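#' Pipeline configuration
#'
#' Settings for the per-pair measurement pipeline. The defaults reproduce
#' the study's stated processing choices: maximum-entropy auto-threshold on
#' the pre-treatment scan reused for the post-treatment scan, a median
#' filter of radius two voxels on the mandible-cropped volumes, rigid
#' voxel-based registration, and an automatically proposed condylar-head VOI
#' with a neck/ramus validation VOI directly below it. Either VOI can be
#' overridden manually (as in the original, operator-set workflow).
#'
#' @param n_bins histogram bins for [max_entropy_threshold()].
#' @param median_radius median-filter radius in voxels (0 disables; the
#'   filter exists to suppress acquisition noise).
#' @param fill background gray value used when masking out non-mandible
#'   voxels.
#' @param crop_dilate voxels of dilation applied to the mandible mask before
#'   the intensity crop. A small shell around the bone keeps the
#'   partial-volume edge ramp, which carries the sub-voxel surface position;
#'   a hard crop at the threshold surface would clip it and quantize both
#'   registration and re-segmentation. The shell lies far below the bone
#'   threshold, so measured voxel counts are unaffected.
#' @param metric_dilate voxels of dilation defining the near-bone region of
#'   the pre-treatment mandible to which the registration metric is
#'   restricted (must be smaller than `crop_dilate`).
#' @param neck_height validation-VOI height in voxel slices.
#' @param pad lateral padding of the auto head VOI in voxels.
#' @param head_voi,validation_voi optional manual [voi_box()]es on the
#'   pre-treatment grid; both must be given together.
#' @param threshold optional manual gray-value threshold (skips
#'   auto-thresholding).
#' @param registration settings from [register_params()].
#' @param seed integer seed recorded with the run.
#' @param output_dir optional directory: when set, [run_pair()] persists the
#'   record, masks, transform, threshold and a run log there.
#' @param keep_masks if `TRUE`, attach head masks and difference masks to
#'   the returned record (as attributes).
#' @export
pipeline_config <- function(n_bins = 256L,
                            median_radius = 2L,
                            fill = 0,
                            crop_dilate = 4L,
                            metric_dilate = 2L,
                            neck_height = 20L,
                            pad = 2L,
                            head_voi = NULL,
                            validation_voi = NULL,
                            threshold = NULL,
                            registration = register_params(),
                            seed = 1L,
                            output_dir = NULL,
                            keep_masks = FALSE) {
  if (xor(is.null(head_voi), is.null(validation_voi)))
    stop("manual VOIs must be given as a pair (head + validation)", call. = FALSE)
  if (metric_dilate > crop_dilate)
    stop("metric_dilate must not exceed crop_dilate", call. = FALSE)
  list(n_bins = as.integer(n_bins), median_radius = as.integer(median_radius),
       fill = fill, crop_dilate = as.integer(crop_dilate),
       metric_dilate = as.integer(metric_dilate),
       neck_height = as.integer(neck_height), pad = as.integer(pad),
       head_voi = head_voi, validation_voi = validation_voi,
       threshold = threshold, registration = registration,
       seed = as.integer(seed), output_dir = output_dir,
       keep_masks = isTRUE(keep_masks))
}

#' Measure condylar volume change for one pre/post pair
#'
#' Runs the full per-joint pipeline: read both volumes, auto-threshold the
#' pre-treatment scan by maximum entropy, segment bone in both scans with
#' that one threshold, keep the mandibular connected component, crop the
#' original intensities by the mandible mask, median-filter, rigidly
#' register the post-treatment mandible to the pre-treatment mandible,
#' resample it onto the pre-treatment grid, set the common condylar-head VOI
#' (auto-proposed or manual) plus the neck/ramus validation VOI directly
#' below, re-segment the cropped heads with the saved threshold, and count
#' the overlap decomposition. The validation VOI's residual disagreement
#' (`validation_delta` out of `validation_total` bone voxels) quantifies
#' segmentation/registration error where true change is assumed negligible.
#'
#' @param pre,post file paths (NRRD/NIfTI) or [voxel_volume()] objects.
#' @param dT_months scan interval in months, carried into the record.
#' @param config a [pipeline_config()].
#' @return A one-row tibble: the [measure_change()] record plus
#'   `validation_delta`, `validation_total`, `threshold` and the pose
#'   summary of the recovered transform. The transform, VOIs and (with
#'   `keep_masks`) the masks are attached as attributes.
#' @export
run_pair <- function(pre, post, dT_months = NA_real_,
                     config = pipeline_config()) {
  stage <- "read"
  out <- tryCatch({
    pre_vol <- if (is_cv_volume(pre)) pre else read_volume(pre)
    post_vol <- if (is_cv_volume(post)) post else read_volume(post)

    stage <- "threshold"
    thr <- if (!is.null(config$threshold)) config$threshold
           else max_entropy_threshold(pre_vol, config$n_bins)
    thr_value <- if (inherits(thr, "cv_threshold")) thr$threshold else thr

    stage <- "segment"
    pre_bone <- segment_bone(pre_vol, thr_value)
    post_bone <- segment_bone(post_vol, thr_value)  # threshold reuse

    stage <- "select_mandible"
    pre_mand <- select_mandible(pre_bone)
    post_mand <- select_mandible(post_bone)

    stage <- "crop_by_mask"
    pre_crop <- crop_by_mask(pre_vol, dilate_mask(pre_mand, config$crop_dilate),
                             config$fill)
    post_crop <- crop_by_mask(post_vol,
                              dilate_mask(post_mand, config$crop_dilate),
                              config$fill)

    stage <- "median_filter"
    pre_filt <- median_filter_3d(pre_crop, config$median_radius)
    post_filt <- median_filter_3d(post_crop, config$median_radius)

    stage <- "register"
    transform <- register_rigid(pre_filt, post_filt, config$registration,
                                fixed_mask = dilate_mask(pre_mand,
                                                         config$metric_dilate))

    stage <- "resample"
    post_aligned <- resample(post_filt, transform, reference = pre_filt,
                             interpolation = "cubic", fill = config$fill)

    stage <- "voi"
    pre_mask_full <- segment_bone(pre_filt, thr_value)
    post_mask_full <- segment_bone(post_aligned, thr_value)
    if (!is.null(config$head_voi)) {
      vois <- list(head = config$head_voi, validation = config$validation_voi)
    } else {
      vois <- auto_head_voi(pre_mask_full, post_mask_full,
                            neck_height = config$neck_height, pad = config$pad)
    }

    stage <- "measure"
    pre_head <- segment_bone(crop_voi(pre_filt, vois$head), thr_value)
    post_head <- segment_bone(crop_voi(post_aligned, vois$head), thr_value)
    record <- measure_change(pre_head, post_head, dT_months)

    stage <- "validate"
    pre_val <- segment_bone(crop_voi(pre_filt, vois$validation), thr_value)
    post_val <- segment_bone(crop_voi(post_aligned, vois$validation), thr_value)
    vdelta <- sum(xor(pre_val$data, post_val$data))
    vtotal <- sum(pre_val$data | post_val$data)

    pose <- transform_magnitude(transform)
    record$validation_delta <- vdelta
    record$validation_total <- vtotal
    record$threshold <- thr_value
    record$reg_rotation_deg <- pose[["angle_deg"]]
    record$reg_displacement_mm <- pose[["displacement_mm"]]
    attr(record, "transform") <- transform
    attr(record, "vois") <- vois
    if (config$keep_masks) {
      attr(record, "masks") <- c(list(pre_head = pre_head, post_head = post_head),
                                 change_masks(pre_head, post_head))
    }
    if (!is.null(config$output_dir))
      persist_pair(record, transform, thr, vois, pre_head, post_head, config)
    record
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  out
}

persist_pair <- function(record, transform, thr, vois, pre_head, post_head,
                         config) {
  dir <- config$output_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(record, file.path(dir, "record.csv"), row.names = FALSE)
  write_transform(transform, file.path(dir, "transform.json"))
  if (inherits(thr, "cv_threshold"))
    write_threshold(thr, file.path(dir, "threshold.json"))
  write_volume(pre_head, file.path(dir, "pre_head_mask.nrrd"))
  write_volume(post_head, file.path(dir, "post_head_mask.nrrd"))
  diffm <- change_masks(pre_head, post_head)
  write_volume(diffm$resorption, file.path(dir, "dv_minus_mask.nrrd"))
  write_volume(diffm$deposition, file.path(dir, "dv_plus_mask.nrrd"))
  jsonlite::write_json(
    list(seed = config$seed, n_bins = config$n_bins,
         median_radius = config$median_radius, fill = config$fill,
         neck_height = config$neck_height, pad = config$pad,
         metric = config$registration$metric,
         threshold = record$threshold,
         head_voi = list(lower = vois$head$lower, upper = vois$head$upper),
         validation_voi = list(lower = vois$validation$lower,
                               upper = vois$validation$upper)),
    file.path(dir, "run_config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the pipeline over a cohort manifest
#'
#' Measures every pre/post pair of a manifest, joins the per-condyle records
#' with the manifest's clinical covariates and runs the staged analysis
#' plan. Per-row failures are logged and skipped; the run fails only if all
#' rows fail.
#'
#' @param manifest a data frame (or CSV path) with columns `pre_path`,
#'   `post_path`, optionally `dT_months`, `condyle_id` and the clinical
#'   covariate columns of [make_cohort_table()].
#' @param config a [pipeline_config()]; when `output_dir` is set, one
#'   self-describing subdirectory per pair plus the cohort CSV and the
#'   statistics report are written there.
#' @return A list with `records` (tibble of per-condyle measurements joined
#'   to covariates), `report` (a `condyle_report`, or `NULL` when the
#'   covariates needed for the plan are absent) and `failures`.
#' @export
run_cohort <- function(manifest, config = pipeline_config()) {
  if (is.character(manifest)) manifest <- read_cohort(manifest)
  manifest <- tibble::as_tibble(manifest)
  stopifnot(all(c("pre_path", "post_path") %in% names(manifest)))
  root <- config$output_dir
  records <- vector("list", nrow(manifest))
  failures <- character()
  for (i in seq_len(nrow(manifest))) {
    cfg <- config
    cfg$output_dir <- if (is.null(root)) NULL
                      else file.path(root, sprintf("pair_%03d", i))
    rec <- tryCatch(
      run_pair(manifest$pre_path[i], manifest$post_path[i],
               dT_months = manifest$dT_months[i] %||% NA_real_, config = cfg),
      error = function(e) {
        warning("manifest row ", i, " skipped: ", conditionMessage(e),
                call. = FALSE)
        failures <<- c(failures, paste0("row ", i, ": ", conditionMessage(e)))
        NULL
      })
    if (!is.null(rec)) {
      rec$manifest_row <- i
      records[[i]] <- rec
    }
  }
  records <- dplyr::bind_rows(records)
  if (nrow(records) == 0)
    stop("all ", nrow(manifest), " manifest rows failed", call. = FALSE)
  covars <- manifest[records$manifest_row,
                     setdiff(names(manifest), c("pre_path", "post_path",
                                                "dT_months")),
                     drop = FALSE]
  records <- dplyr::bind_cols(records, covars)
  report <- NULL
  if (all(c("erosion", "pain", "patient_id") %in% names(records)))
    report <- run_analysis_plan(records)
  if (!is.null(root)) {
    dir.create(root, showWarnings = FALSE, recursive = TRUE)
    write_cohort(records, file.path(root, "cohort_records.csv"))
    if (!is.null(report)) write_report(report, file.path(root, "stats"))
    writeLines(failures, file.path(root, "failures.log"))
  }
  list(records = records, report = report, failures = failures)
}
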