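#' Axis-aligned volume-of-interest box
#'
#' A VOI is an axis-aligned box on the canonical (pre-treatment) grid, given
#' as 1-based voxel indices, half-open per axis: voxel index `i` belongs to
#' the box when `lower[a] <= i < upper[a]` on every axis `a`.
#'
#' @param lower,upper integer length-3 index bounds, `lower < upper` per axis.
#' @return An object of class `cv_voi`.
#' @export
voi_box <- function(lower, upper) {
  lower <- as.integer(lower); upper <- as.integer(upper)
  stopifnot(length(lower) == 3, length(upper) == 3)
  if (any(lower >= upper))
    stop("VOI must satisfy lower < upper on every axis", call. = FALSE)
  if (any(lower < 1L))
    stop("VOI lower bound must be >= 1", call. = FALSE)
  structure(list(lower = lower, upper = upper), class = "cv_voi")
}

#' @export
print.cv_voi <- function(x, ...) {
  cat("<cv_voi> [", paste(x$lower, collapse = ", "), ") -> [",
      paste(x$upper, collapse = ", "), "), shape ",
      paste(x$upper - x$lower, collapse = " x "), "\n", sep = "")
  invisible(x)
}

#' Crop a volume or mask to a VOI
#'
#' The output grid has the VOI's extents and an origin advanced to the VOI's
#' lower corner, so physical coordinates are preserved.
#'
#' @param input a [voxel_volume()] or [binary_mask()].
#' @param voi a [voi_box()] lying within the grid.
#' @return Same kind of object as `input`.
#' @export
crop_voi <- function(input, voi) {
  stopifnot(inherits(voi, "cv_voi"))
  d <- dim(input$data)
  if (any(voi$upper > d + 1L))
    stop("VOI exceeds grid bounds (grid ", paste(d, collapse = "x"), ")",
         call. = FALSE)
  sub <- input$data[voi$lower[1]:(voi$upper[1] - 1L),
                    voi$lower[2]:(voi$upper[2] - 1L),
                    voi$lower[3]:(voi$upper[3] - 1L), drop = FALSE]
  origin <- input$origin + (voi$lower - 1L) * input$spacing
  if (is_cv_mask(input)) binary_mask(sub, input$spacing, origin)
  else voxel_volume(sub, input$spacing, origin)
}

#' Propose the condylar-head and validation VOIs
#'
#' With the two mandibles superimposed on the pre-treatment grid, the
#' condylar-head VOI is the bounding box of the superior portion of the union
#' mask, extending down to the narrowest axial cross-section below the head
#' (the condylar neck waist) and padded laterally; the validation VOI (the
#' condylar neck / ramus region where true change is assumed negligible)
#' shares the transverse extents and spans `neck_height` voxel slices
#' directly inferior, with zero gap. The superior axis is the third (z) axis.
#'
#' @param pre_mask,post_mask_in_pre_frame nonempty [binary_mask()] objects on
#'   the same (pre-treatment) grid.
#' @param neck_height height of the validation VOI in voxel slices.
#' @param pad lateral padding of the head box in voxels.
#' @return A list with elements `head` and `validation`, both [voi_box()]
#'   objects; `validation$upper[3] == head$lower[3]`.
#' @export
auto_head_voi <- function(pre_mask, post_mask_in_pre_frame, neck_height = 20L,
                          pad = 2L) {
  stopifnot(is_cv_mask(pre_mask), is_cv_mask(post_mask_in_pre_frame))
  stopifnot_same_geometry(pre_mask, post_mask_in_pre_frame)
  u <- pre_mask$data | post_mask_in_pre_frame$data
  if (!any(u)) stop("masks are empty", call. = FALSE)
  d <- dim(u)
  area <- apply(u, 3, sum)
  occ <- which(area > 0)
  z_top <- max(occ)
  z_peak <- which.max(area)  # widest cross-section: the head's equator/base
  below <- seq_len(z_peak - 1L)
  below <- below[area[below] > 0]
  # the neck waist is an *interior* minimum: wider cross-sections must exist
  # both above (the head) and below (the ramus); this keeps the tapering
  # bottom edge of the mask from masquerading as the waist
  run_max <- cummax(c(0, area))[below]  # widest slice strictly below each z
  below <- below[run_max > area[below]]
  if (length(below) == 0)
    stop("mask too short: no neck below the condylar head", call. = FALSE)
  waist_area <- min(area[below])
  z_waist <- max(below[area[below] == waist_area])  # nearest the head
  if (z_waist - neck_height < 1L)
    stop("mask too short: validation VOI of ", neck_height,
         " slices does not fit below the head VOI", call. = FALSE)

  slab <- u[, , z_waist:z_top, drop = FALSE]
  w <- which(apply(slab, 1, any))
  x_rng <- c(min(w), max(w))
  w <- which(apply(slab, 2, any))
  y_rng <- c(min(w), max(w))
  lower_xy <- pmax(c(x_rng[1], y_rng[1]) - pad, 1L)
  upper_xy <- pmin(c(x_rng[2], y_rng[2]) + pad, d[1:2]) + 1L
  head <- voi_box(c(lower_xy, z_waist), c(upper_xy, z_top + 1L))
  validation <- voi_box(c(lower_xy, z_waist - neck_height),
                        c(upper_xy, z_waist))
  list(head = head, validation = validation)
}

#' Does a VOI contain every true voxel of a mask?
#'
#' @param voi a [voi_box()].
#' @param mask a [binary_mask()].
#' @export
voi_contains_mask <- function(voi, mask) {
  w <- which(mask$data, arr.ind = TRUE)
  if (nrow(w) == 0) return(TRUE)
  all(sweep(w, 2, voi$lower, `>=`)) && all(sweep(w, 2, voi$upper, `<`))
}
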