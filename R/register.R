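#' Registration settings
#'
#' Settings for [register_rigid()]. The defaults implement a standard robust
#' recipe for same-scanner CBCT-to-CBCT rigid alignment: a 3-level
#' multi-resolution pyramid (shrink factors 4/2/1 with Gaussian smoothing of
#' 2/1/0 voxels), center-of-mass initialization, Nelder-Mead exploration at
#' the coarsest level and quasi-Newton (BFGS) refinement at every level.
#'
#' The default similarity metric is the mean-squared intensity difference,
#' appropriate for longitudinal pairs acquired on one scanner under one
#' protocol; `metric = "mi"` selects a histogram-based mutual-information
#' metric for pairs with gray-value drift.
#'
#' @param metric `"meansquares"` or `"mi"`.
#' @param shrink integer shrink factor per pyramid level (coarse to fine).
#' @param smooth Gaussian smoothing sigma in voxels per level.
#' @param max_iter optimizer iteration cap per level.
#' @param mi_bins number of histogram bins for the MI metric.
#' @param fill background gray value assumed outside the moving volume.
#' @param trim if `TRUE` (default, mean-squares only), a robust second pass
#'   at the finest level excludes voxels whose residual at the first-pass
#'   optimum exceeds half the fixed-image intensity range. Longitudinal
#'   pairs contain genuine change (the lesion); without trimming that
#'   unmodeled change biases the pose toward partially "explaining" it.
#' @param seed integer seed; the metric is evaluated over all voxels (no
#'   stochastic sampling), so this is recorded for provenance only.
#' @export
register_params <- function(metric = c("meansquares", "mi"),
                            shrink = c(4L, 2L, 1L),
                            smooth = c(2, 1, 0),
                            max_iter = 500L,
                            mi_bins = 32L,
                            fill = 0,
                            trim = TRUE,
                            seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(length(shrink) == length(smooth), all(shrink >= 1))
  list(metric = metric, shrink = as.integer(shrink), smooth = smooth,
       max_iter = as.integer(max_iter), mi_bins = as.integer(mi_bins),
       fill = fill, trim = isTRUE(trim), seed = as.integer(seed))
}

#' Rigid intensity-based registration
#'
#' Estimates the 6-DOF rigid transform aligning a moving volume to a fixed
#' volume by multi-resolution optimization of an intensity-similarity metric.
#' In the pipeline the *pre-treatment* mandible (cropped and median-filtered)
#' is the fixed image and the *post-treatment* mandible the moving image, so
#' the returned transform maps pre-treatment physical points into the
#' post-treatment frame and [resample()] pulls the post volume onto the
#' pre-treatment grid.
#'
#' The result is deterministic for given inputs and settings: the metric is
#' evaluated densely (no stochastic sampling).
#'
#' @param fixed,moving nonconstant [voxel_volume()] objects with overlapping
#'   fields of view.
#' @param params settings from [register_params()].
#' @param fixed_mask optional [binary_mask()] on the fixed grid restricting
#'   the metric to those fixed voxels. Restricting the metric to a
#'   neighborhood of the structure of interest keeps crop boundaries and
#'   empty background out of the similarity measure.
#' @return A [rigid_transform()] with attributes `metric` (final metric
#'   value), `iterations` (function evaluations per level) and `converged`.
#' @export
register_rigid <- function(fixed, moving, params = register_params(),
                           fixed_mask = NULL) {
  stopifnot(is_cv_volume(fixed), is_cv_volume(moving))
  if (diff(range(fixed$data)) == 0 || diff(range(moving$data)) == 0)
    stop("degenerate input: constant volume cannot be registered", call. = FALSE)
  if (!is.null(fixed_mask)) {
    stopifnot(is_cv_mask(fixed_mask))
    stopifnot_same_geometry(fixed, fixed_mask)
  }

  center <- center_of_mass(shifted_nonneg(fixed))
  com_moving <- center_of_mass(shifted_nonneg(moving))
  theta <- c(0, 0, 0, com_moving - center)  # center-of-mass initialization

  nlevels <- length(params$shrink)
  iters <- integer(nlevels)
  value <- NA_real_
  for (lv in seq_len(nlevels)) {
    f <- pyramid_level(fixed, params$shrink[lv], params$smooth[lv])
    m <- pyramid_level(moving, params$shrink[lv], params$smooth[lv])
    lv_mask <- if (is.null(fixed_mask)) logical(0)
               else as.logical(subsample_mask(fixed_mask, params$shrink[lv]))
    bb <- if (is.null(fixed_mask)) content_bbox(f, params$fill, pad = 4L)
          else mask_bbox(array(lv_mask, dim(f$data)))
    obj <- metric_fun(f, m, bb, center, params, include = lv_mask)

    if (lv == 1L) {
      nm <- stats::optim(theta, obj, method = "Nelder-Mead",
                         control = list(maxit = params$max_iter, reltol = 1e-10))
      theta <- nm$par
      iters[lv] <- iters[lv] + nm$counts[["function"]]
    }
    bf <- stats::optim(theta, obj, method = "BFGS",
                       control = list(maxit = params$max_iter, reltol = 1e-14,
                                      ndeps = rep(1e-3, 6)))
    theta <- bf$par
    iters[lv] <- iters[lv] + bf$counts[["function"]]
    value <- bf$value
    if (bf$convergence != 0 && lv == nlevels)
      stop("registration optimizer did not converge (final metric ", value,
           ", ", iters[lv], " evaluations at the finest level)", call. = FALSE)

    if (lv == nlevels && params$trim && params$metric == "meansquares") {
      # robust pass: drop voxels whose residual looks like genuine change
      include <- residual_include(f, m, theta, center, params)
      if (length(lv_mask) > 0) include <- include & lv_mask
      obj2 <- metric_fun(f, m, bb, center, params, include = include)
      bf <- stats::optim(theta, obj2, method = "BFGS",
                         control = list(maxit = params$max_iter,
                                        reltol = 1e-14, ndeps = rep(1e-3, 6)))
      theta <- bf$par
      iters[lv] <- iters[lv] + bf$counts[["function"]]
      value <- bf$value
    }
  }
  out <- rigid_transform(theta[1:3], theta[4:6], center)
  attr(out, "metric") <- value
  attr(out, "iterations") <- iters
  attr(out, "converged") <- TRUE
  out
}

# intensities shifted so the center-of-mass weights are nonnegative
shifted_nonneg <- function(vol) {
  mn <- min(vol$data)
  if (mn >= 0) return(vol)
  voxel_volume(vol$data - mn, vol$spacing, vol$origin)
}

metric_fun <- function(f, m, bb, center, params, include = logical(0)) {
  fdat <- as.numeric(f$data); fdim <- dim(f$data)
  mdat <- as.numeric(m$data); mdim <- dim(m$data)
  if (params$metric == "meansquares") {
    function(theta) {
      af <- transform_affine(rigid_transform(theta[1:3], theta[4:6], center))
      cpp_metric_ssd(fdat, fdim, f$spacing, f$origin, mdat, mdim, m$spacing,
                     m$origin, af$A, af$b, bb$lo, bb$hi, params$fill, include)
    }
  } else {
    f_range <- range(fdat)
    m_range <- range(c(mdat, params$fill))
    function(theta) {
      af <- transform_affine(rigid_transform(theta[1:3], theta[4:6], center))
      cpp_metric_nmi(fdat, fdim, f$spacing, f$origin, mdat, mdim, m$spacing,
                     m$origin, af$A, af$b, bb$lo, bb$hi, params$fill,
                     params$mi_bins, f_range, m_range, include)
    }
  }
}

# voxels to keep in the robust pass: residual at the current optimum below
# half the fixed-image intensity range (partial-volume and noise residuals
# pass; resorbed/deposited bone, at full contrast, is excluded)
residual_include <- function(f, m, theta, center, params) {
  aligned <- resample(m, rigid_transform(theta[1:3], theta[4:6], center),
                      reference = f, interpolation = "linear",
                      fill = params$fill)
  cutoff <- 0.5 * diff(range(f$data))
  as.logical(abs(f$data - aligned$data) <= cutoff)
}

# smooth then stride-subsample; the first voxel center is retained so the
# origin is unchanged and the spacing scales by the shrink factor
pyramid_level <- function(vol, shrink, smooth_vox) {
  v <- if (smooth_vox > 0) {
    out <- cpp_gaussian_blur(as.numeric(vol$data), dim(vol$data),
                             rep(smooth_vox, 3))
    voxel_volume(array(out, dim(vol$data)), vol$spacing, vol$origin)
  } else vol
  if (shrink == 1L) return(v)
  d <- dim(v$data)
  idx <- lapply(d, function(n) seq(1L, n, by = shrink))
  voxel_volume(v$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE],
               v$spacing * shrink, v$origin)
}

# stride-subsample a mask to a pyramid level's grid
subsample_mask <- function(mask, shrink) {
  if (shrink == 1L) return(mask$data)
  d <- dim(mask$data)
  idx <- lapply(d, function(n) seq(1L, n, by = shrink))
  mask$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# 0-based inclusive bounding box of a logical array's TRUE voxels
mask_bbox <- function(arr, pad = 0L) {
  if (!any(arr)) return(list(lo = c(0L, 0L, 0L), hi = dim(arr) - 1L))
  w <- which(arr, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - 1L - pad, 0L)
  hi <- pmin(apply(w, 2, max) - 1L + pad, dim(arr) - 1L)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

# 0-based inclusive bounding box of voxels deviating from the background
content_bbox <- function(vol, fill, pad = 4L) {
  d <- dim(vol$data)
  tol <- 1e-9 * max(1, diff(range(vol$data)))
  hit <- abs(vol$data - fill) > tol
  if (!any(hit)) return(list(lo = c(0L, 0L, 0L), hi = d - 1L))
  w <- which(hit, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - 1L - pad, 0L)
  hi <- pmin(apply(w, 2, max) - 1L + pad, d - 1L)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

#' Resample a volume or mask through a rigid transform
#'
#' Pulls the input onto `reference`'s grid: each output voxel takes the input
#' value at the transformed position of its physical center. Voxels mapping
#' outside the input domain get `fill` (0 / `FALSE`). Masks must use
#' nearest-neighbor interpolation; volumes default to trilinear.
#'
#' @param input a [voxel_volume()] or [binary_mask()].
#' @param transform a [rigid_transform()] mapping reference-space points into
#'   input-space points (the pull convention; see [register_rigid()]).
#' @param reference a volume/mask (or [geometry()] list) defining the output
#'   grid; defaults to the input's own grid.
#' @param interpolation `"linear"`, `"cubic"` (Catmull-Rom, the measurement
#'   default for gray volumes: it preserves smooth edge profiles that the
#'   trilinear tent kernel smears) or `"nearest"`; masks require
#'   `"nearest"`.
#' @param fill background value for out-of-domain voxels.
#' @return Same kind of object as `input`, on the reference grid.
#' @export
resample <- function(input, transform, reference = NULL,
                     interpolation = NULL, fill = 0) {
  is_mask <- is_cv_mask(input)
  if (!is_mask && !is_cv_volume(input))
    stop("`input` must be a cv_volume or cv_mask", call. = FALSE)
  if (is.null(interpolation)) interpolation <- if (is_mask) "nearest" else "linear"
  interpolation <- match.arg(interpolation, c("linear", "nearest", "cubic"))
  if (is_mask && interpolation != "nearest")
    stop("masks must be resampled with nearest-neighbor interpolation", call. = FALSE)
  ref <- if (is.null(reference)) geometry(input)
         else if (is_cv_volume(reference) || is_cv_mask(reference)) geometry(reference)
         else reference
  af <- transform_affine(transform)
  interp_code <- match(interpolation, c("linear", "nearest", "cubic")) - 1L
  out <- cpp_resample(as.numeric(input$data), dim(input$data), input$spacing,
                      input$origin, as.integer(ref$shape), ref$spacing,
                      ref$origin, af$A, af$b, interp_code, as.numeric(fill))
  arr <- array(out, ref$shape)
  if (is_mask) binary_mask(arr > 0.5, ref$spacing, ref$origin)
  else voxel_volume(arr, ref$spacing, ref$origin)
}
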