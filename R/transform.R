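#' Rigid (6-DOF) spatial transforms
#'
#' A proper rigid motion parameterized by three rotation angles (degrees,
#' applied about the x, then y, then z axis of the fixed LPS frame, i.e.
#' `R = Rz %*% Ry %*% Rx`), a translation (mm) and a rotation center (mm).
#' A point `p` maps to `R (p - center) + center + translation`.
#'
#' In this package a transform is always read in the pull (resampling)
#' convention: it maps points of the *fixed* (output) space into the *moving*
#' (input) space. The transform estimated by [register_rigid()] therefore maps
#' pre-treatment coordinates onto post-treatment coordinates, and resampling
#' the post volume through it brings it onto the pre-treatment grid.
#'
#' @param rotation numeric length-3, rotation angles in degrees.
#' @param translation numeric length-3, translation in mm.
#' @param center numeric length-3, rotation center in mm.
#' @return An object of class `cv_rigid`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotation) == 3, length(translation) == 3, length(center) == 3)
  structure(
    list(rotation = as.numeric(rotation), translation = as.numeric(translation),
         center = as.numeric(center)),
    class = "cv_rigid"
  )
}

rotation_matrix <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

angles_from_matrix <- function(R) {
  # inverse of rotation_matrix (R = Rz Ry Rx)
  ry <- asin(max(-1, min(1, -R[3, 1])))
  if (abs(cos(ry)) > 1e-12) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal lock
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

#' Affine form of a rigid transform
#'
#' Returns the transform as `list(A, b)` with `A` a 3x3 rotation matrix and
#' `b` an offset so that a point maps to `A p + b`.
#'
#' @param transform a [rigid_transform()].
#' @export
transform_affine <- function(transform) {
  A <- rotation_matrix(transform$rotation)
  b <- transform$center + transform$translation - as.numeric(A %*% transform$center)
  list(A = A, b = b)
}

#' Apply a rigid transform to physical points
#'
#' @param transform a [rigid_transform()].
#' @param points numeric length-3 vector or n-by-3 matrix of points (mm).
#' @return Transformed points, same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  af <- transform_affine(transform)
  vec <- is.null(dim(points))
  if (vec) points <- matrix(points, nrow = 1)
  out <- t(af$A %*% t(points)) + matrix(af$b, nrow(points), 3, byrow = TRUE)
  if (vec) as.numeric(out) else out
}

#' Invert a rigid transform
#'
#' The composition of a transform with its inverse maps any point to itself
#' (to within floating-point error, well under 1e-6 mm).
#'
#' @param transform a [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  af <- transform_affine(transform)
  Ai <- t(af$A)
  bi <- -as.numeric(Ai %*% af$b)
  affine_to_rigid(Ai, bi, transform$center)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(t1, t2)` returns the transform applying `t2` first,
#' then `t1` (i.e. `p -> t1(t2(p))`).
#'
#' @param t1,t2 [rigid_transform()] objects.
#' @export
compose_transforms <- function(t1, t2) {
  a1 <- transform_affine(t1)
  a2 <- transform_affine(t2)
  A <- a1$A %*% a2$A
  b <- as.numeric(a1$A %*% a2$b) + a1$b
  affine_to_rigid(A, b, t1$center)
}

affine_to_rigid <- function(A, b, center) {
  rot <- angles_from_matrix(A)
  # b = c + t - A c  =>  t = b - c + A c
  tr <- b - center + as.numeric(A %*% center)
  rigid_transform(rot, tr, center)
}

#' Magnitude of a rigid transform
#'
#' Summarizes a transform as its overall rotation angle (degrees) and the
#' displacement (mm) it applies at a reference point — used to compare a
#' recovered registration against a known truth pose.
#'
#' @param transform a [rigid_transform()].
#' @param at physical point (mm) at which displacement is measured; default
#'   the transform's own center.
#' @return Named numeric vector `c(angle_deg, displacement_mm)`.
#' @export
transform_magnitude <- function(transform, at = transform$center) {
  A <- rotation_matrix(transform$rotation)
  ca <- (sum(diag(A)) - 1) / 2
  angle <- acos(max(-1, min(1, ca))) * 180 / pi
  disp <- sqrt(sum((apply_transform(transform, at) - at)^2))
  c(angle_deg = angle, displacement_mm = disp)
}

#' Serialize / deserialize a rigid transform
#'
#' Transforms are written as a small JSON sidecar (rotations in degrees,
#' translation and center in mm, plus the equivalent homogeneous 4x4 matrix
#' for interoperability).
#'
#' @param transform a [rigid_transform()].
#' @param path file path for the JSON sidecar.
#' @export
write_transform <- function(transform, path) {
  af <- transform_affine(transform)
  m4 <- rbind(cbind(af$A, af$b), c(0, 0, 0, 1))
  jsonlite::write_json(
    list(
      convention = "pull: fixed-space point -> moving-space point; LPS mm; R = Rz Ry Rx",
      rotation_deg = transform$rotation,
      translation_mm = transform$translation,
      center_mm = transform$center,
      matrix4 = m4
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$rotation_deg, x$translation_mm, x$center_mm)
}

#' @export
print.cv_rigid <- function(x, ...) {
  cat("<cv_rigid> rotation (deg): ", paste(signif(x$rotation, 5), collapse = ", "),
      "\n  translation (mm): ", paste(signif(x$translation, 5), collapse = ", "),
      "\n  center (mm): ", paste(signif(x$center, 5), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
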