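#' Maximum-entropy (Kapur) automatic threshold
#'
#' Chooses the gray-value threshold that maximizes the sum of Shannon
#' entropies of the sub- and supra-threshold partitions of the intensity
#' histogram (the Kapur-Sahoo-Wong criterion). This is the automatic
#' thresholding used to segment bone from the pre-treatment CBCT; the same
#' threshold is then reused on the post-treatment scan of the same joint so
#' that both timepoints are segmented identically.
#'
#' The histogram uses `n_bins` uniform bins over the occupied intensity range.
#' Candidate thresholds are the interior bin boundaries; candidates leaving an
#' empty side are skipped. When several candidates tie for the maximum (which
#' happens systematically for well-separated bimodal histograms, where the
#' criterion is flat between the modes), the middle candidate of the tied set
#' is returned: it maximizes the margin to both modes, whereas an endpoint of
#' the plateau would sit arbitrarily close to one of them.
#'
#' @param volume a [voxel_volume()] with at least two distinct intensities.
#' @param n_bins number of histogram bins (>= 2); default 256.
#' @return An object of class `cv_threshold`: a list with `threshold` (gray
#'   value), `histogram` (`breaks`, `counts`) and `criterion_curve` (entropy
#'   sum per candidate boundary, `NA` where a side is empty).
#' @examples
#' v <- voxel_volume(array(c(rep(100, 400), rep(1000, 100)), c(10, 10, 5)))
#' max_entropy_threshold(v)$threshold
#' @export
max_entropy_threshold <- function(volume, n_bins = 256) {
  stopifnot(is_cv_volume(volume))
  if (n_bins < 2) stop("`n_bins` must be at least 2", call. = FALSE)
  vals <- as.numeric(volume$data)
  rng <- range(vals)
  if (rng[1] == rng[2])
    stop("degenerate input: volume is constant, no threshold exists", call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- pmin(pmax(findInterval(vals, breaks, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  p <- counts / sum(counts)

  entropy_cum <- function(prob) {
    # cumulative sum of -p log p over bins (0 bins contribute 0)
    h <- ifelse(prob > 0, -prob * log(prob), 0)
    cumsum(h)
  }
  hcum <- entropy_cum(p)
  htot <- hcum[n_bins]
  P0 <- cumsum(p)
  crit <- rep(NA_real_, n_bins - 1)
  for (s in seq_len(n_bins - 1)) {
    p0 <- P0[s]
    p1 <- 1 - p0
    if (p0 <= 0 || p1 <= 0) next  # empty-side candidate
    # entropy of renormalized partition: H(p/P) = (1/P) * sum(-p log p) + log P
    h_below <- hcum[s] / p0 + log(p0)
    h_above <- (htot - hcum[s]) / p1 + log(p1)
    crit[s] <- h_below + h_above
  }
  if (all(is.na(crit)))
    stop("degenerate input: no valid threshold candidate", call. = FALSE)
  tied <- which(abs(crit - max(crit, na.rm = TRUE)) < 1e-12)
  best <- tied[ceiling(length(tied) / 2)]  # ties -> middle of the plateau
  structure(
    list(
      threshold = breaks[best + 1],
      histogram = list(breaks = breaks, counts = counts),
      criterion_curve = crit
    ),
    class = "cv_threshold"
  )
}

#' @export
print.cv_threshold <- function(x, ...) {
  cat("<cv_threshold> maximum-entropy threshold = ", signif(x$threshold, 8),
      " (", length(x$histogram$counts), " bins over [",
      signif(x$histogram$breaks[1], 6), ", ",
      signif(x$histogram$breaks[length(x$histogram$breaks)], 6), "])\n", sep = "")
  invisible(x)
}

#' Serialize a threshold result to JSON
#'
#' @param x a `cv_threshold`.
#' @param path output path.
#' @export
write_threshold <- function(x, path) {
  jsonlite::write_json(
    list(threshold = x$threshold, breaks = x$histogram$breaks,
         counts = x$histogram$counts, criterion_curve = x$criterion_curve),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' Segment bone at a gray-value threshold
#'
#' Returns the mask of voxels with intensity greater than or equal to the
#' threshold (the threshold voxel itself counts as bone). Geometry is copied
#' from the volume. An empty mask is legal.
#'
#' @param volume a [voxel_volume()].
#' @param threshold gray value, or a `cv_threshold` from
#'   [max_entropy_threshold()].
#' @return A [binary_mask()].
#' @export
segment_bone <- function(volume, threshold) {
  stopifnot(is_cv_volume(volume))
  if (inherits(threshold, "cv_threshold")) threshold <- threshold$threshold
  binary_mask(volume$data >= threshold, volume$spacing, volume$origin)
}

#' Select the mandibular connected component
#'
#' Keeps a single 26-connected component of a bone mask: the component
#' containing `seed_point` when given, otherwise the largest. This removes
#' the cranial structures (glenoid fossa, zygomatic arch) that share the
#' CBCT field of view with the mandible.
#'
#' @param mask a nonempty [binary_mask()].
#' @param seed_point optional 1-based voxel index (length-3 integer) inside
#'   the component to keep.
#' @return A [binary_mask()] containing exactly one connected component.
#' @export
select_mandible <- function(mask, seed_point = NULL) {
  stopifnot(is_cv_mask(mask))
  if (voxel_count(mask) == 0) stop("mask is empty", call. = FALSE)
  labels <- cpp_label_components(as.logical(mask$data), dim(mask$data))
  if (!is.null(seed_point)) {
    stopifnot(length(seed_point) == 3)
    d <- dim(mask$data)
    if (any(seed_point < 1) || any(seed_point > d))
      stop("seed_point outside the grid", call. = FALSE)
    lab <- labels[seed_point[1] + d[1] * ((seed_point[2] - 1) + d[2] * (seed_point[3] - 1))]
    if (lab == 0) stop("seed_point does not lie inside any component", call. = FALSE)
  } else {
    sizes <- tabulate(labels[labels > 0L])
    lab <- which.max(sizes)  # ties -> first-encountered component
  }
  keep <- array(labels == lab, dim = dim(mask$data))
  binary_mask(keep, mask$spacing, mask$origin)
}

#' Mask a volume, keeping intensities only inside a segment
#'
#' Voxels inside the mask keep their original intensity; all others are set
#' to `fill`. Used to crop the mandible out of the full CBCT before
#' registration.
#'
#' @param volume a [voxel_volume()].
#' @param mask a [binary_mask()] on the same grid.
#' @param fill gray value for voxels outside the mask.
#' @return A [voxel_volume()].
#' @export
crop_by_mask <- function(volume, mask, fill = 0) {
  stopifnot(is_cv_volume(volume), is_cv_mask(mask))
  stopifnot_same_geometry(volume, mask)
  out <- volume$data
  if (is.integer(out) && fill == round(fill)) fill <- as.integer(fill)
  out[!mask$data] <- fill
  voxel_volume(out, volume$spacing, volume$origin)
}

#' 3D median filter
#'
#' Replaces each voxel by the median of the cubic neighborhood of half-width
#' `radius`; the neighborhood is truncated at the grid edges (no padding
#' values are invented). `radius = 0` is the identity. The default radius of
#' two voxels is the pipeline's noise-suppression setting.
#'
#' @param volume a [voxel_volume()].
#' @param radius nonnegative integer neighborhood half-width in voxels.
#' @return A [voxel_volume()].
#' @export
median_filter_3d <- function(volume, radius = 2) {
  stopifnot(is_cv_volume(volume))
  if (length(radius) != 1 || is.na(radius) || radius < 0 || radius != round(radius))
    stop("`radius` must be a nonnegative integer", call. = FALSE)
  if (radius == 0) return(volume)
  out <- cpp_median_filter3(as.numeric(volume$data), dim(volume$data), as.integer(radius))
  voxel_volume(array(out, dim(volume$data)), volume$spacing, volume$origin)
}

#' Dilate a mask by a number of voxels (26-neighborhood)
#'
#' Grows the true voxel set by `voxels` one-voxel 26-connected dilations.
#' The pipeline uses this to crop with a small safety shell around the
#' mandible, so the bone's partial-volume edge ramp is retained.
#'
#' @param mask a [binary_mask()].
#' @param voxels nonnegative integer number of dilation steps.
#' @return A [binary_mask()].
#' @export
dilate_mask <- function(mask, voxels = 1L) {
  stopifnot(is_cv_mask(mask), voxels >= 0)
  out <- mask$data
  for (i in seq_len(voxels)) out <- dilate26(out)
  binary_mask(out, mask$spacing, mask$origin)
}

# internal: separable Gaussian blur with sigma given in mm
gaussian_blur_mm <- function(volume, sigma_mm) {
  if (all(sigma_mm <= 0)) return(volume)
  sig_vox <- rep_len(sigma_mm, 3) / volume$spacing
  out <- cpp_gaussian_blur(as.numeric(volume$data), dim(volume$data), sig_vox)
  voxel_volume(array(out, dim(volume$data)), volume$spacing, volume$origin)
}
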