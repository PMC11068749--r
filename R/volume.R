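#' Voxel volumes and binary masks
#'
#' `voxel_volume()` wraps a 3D scalar array (CBCT gray values) together with
#' its grid geometry; `binary_mask()` does the same for a 3D logical array
#' (a segment: bone, mandible, condylar head). All physical quantities are in
#' millimetres. The physical position of voxel index `(i, j, k)` (1-based, as
#' is idiomatic in R) is `origin + (i - 1, j - 1, k - 1) * spacing`, axis-wise,
#' in a fixed LPS anatomical frame: +x left, +y posterior, +z superior.
#'
#' @param data 3D numeric array (for `voxel_volume`) or array coercible to
#'   logical (for `binary_mask`).
#' @param spacing numeric length-3, strictly positive voxel size per axis (mm).
#' @param origin numeric length-3, physical position of voxel `(1, 1, 1)` (mm).
#' @return An object of class `cv_volume` or `cv_mask` with fields `data`,
#'   `spacing`, `origin`.
#' @examples
#' v <- voxel_volume(array(0, c(4, 4, 4)), spacing = c(0.3, 0.3, 0.3))
#' dim(v)
#' @export
voxel_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  check_geometry_args(data, spacing, origin)
  structure(
    list(data = data, spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = "cv_volume"
  )
}

#' @rdname voxel_volume
#' @export
binary_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  check_geometry_args(data, spacing, origin)
  storage.mode(data) <- "logical"
  if (anyNA(data)) stop("mask contains NA voxels", call. = FALSE)
  structure(
    list(data = data, spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = "cv_mask"
  )
}

check_geometry_args <- function(data, spacing, origin) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite values (mm/voxel)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  invisible(TRUE)
}

is_cv_volume <- function(x) inherits(x, "cv_volume")
is_cv_mask <- function(x) inherits(x, "cv_mask")

#' @export
dim.cv_volume <- function(x) dim(x$data)

#' @export
dim.cv_mask <- function(x) dim(x$data)

#' Grid geometry helpers
#'
#' `geometry()` returns the shape/spacing/origin triple of a volume or mask;
#' `same_geometry()` tests whether two objects live on the same grid (shape
#' equal, spacing and origin within `tol` mm); `stopifnot_same_geometry()`
#' raises an error on mismatch. Masks are only comparable or combinable when
#' their geometry matches — voxelwise operations never broadcast silently.
#'
#' @param x,a,b a `cv_volume` or `cv_mask`.
#' @param tol geometric tolerance in mm.
#' @return `geometry()`: a list with `shape`, `spacing`, `origin`.
#' @export
geometry <- function(x) {
  list(shape = dim(x$data), spacing = x$spacing, origin = x$origin)
}

#' @rdname geometry
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

#' @rdname geometry
#' @export
stopifnot_same_geometry <- function(a, b, tol = 1e-6) {
  if (!same_geometry(a, b, tol))
    stop("geometry mismatch: objects are not on the same voxel grid ",
         "(shape/spacing/origin must agree within ", tol, " mm)", call. = FALSE)
  invisible(TRUE)
}

#' Count true voxels of a mask
#'
#' @param mask a `cv_mask`.
#' @return Integer count of true voxels.
#' @export
voxel_count <- function(mask) {
  stopifnot(is_cv_mask(mask))
  sum(mask$data)
}

#' Physical volume of one voxel (mm^3)
#'
#' @param x a `cv_volume` or `cv_mask`.
#' @export
voxel_size_mm3 <- function(x) prod(x$spacing)

#' Physical coordinates of voxel indices
#'
#' Maps 1-based voxel indices to physical LPS coordinates (mm).
#'
#' @param x a `cv_volume` or `cv_mask`.
#' @param index integer vector of length 3 or an n-by-3 matrix of indices.
#' @return A numeric vector or n-by-3 matrix of physical points.
#' @export
voxel_to_world <- function(x, index) {
  if (is.null(dim(index))) index <- matrix(index, nrow = 1)
  sweep(sweep(index - 1, 2, x$spacing, `*`), 2, x$origin, `+`)
}

#' @export
print.cv_volume <- function(x, ...) {
  cat("<cv_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing (", paste(signif(x$spacing, 4), collapse = ", "),
      ") mm, origin (", paste(signif(x$origin, 4), collapse = ", "), ") mm\n",
      "  intensity range [", signif(min(x$data), 6), ", ",
      signif(max(x$data), 6), "]\n", sep = "")
  invisible(x)
}

#' @export
print.cv_mask <- function(x, ...) {
  n <- sum(x$data)
  cat("<cv_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing (", paste(signif(x$spacing, 4), collapse = ", "),
      ") mm, origin (", paste(signif(x$origin, 4), collapse = ", "), ") mm\n",
      "  ", n, " true voxels (", signif(n * prod(x$spacing), 6), " mm^3)\n",
      sep = "")
  invisible(x)
}

# internal: center of mass of a volume's intensities (physical coords)
center_of_mass <- function(vol) {
  d <- vol$data
  w <- sum(d)
  if (w <= 0) stop("cannot compute center of mass of a non-positive volume", call. = FALSE)
  dims <- dim(d)
  idx <- c(
    sum(rowSums(d, dims = 1) * seq_len(dims[1])),
    sum(apply(d, 2, sum) * seq_len(dims[2])),
    sum(apply(d, 3, sum) * seq_len(dims[3]))
  ) / w
  as.numeric(vol$origin + (idx - 1) * vol$spacing)
}
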