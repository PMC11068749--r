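#' Specification of a synthetic condyle phantom pair
#'
#' Describes a truth-labelled synthetic CBCT pair: a condyle-like bone shape
#' (an ellipsoidal condylar-head cap on a neck/ramus stem, plus a
#' disconnected cranial slab that exercises mandible selection) on a
#' soft-tissue background, with a carved anterior-superior surface-erosion
#' lesion and peripheral deposition between the two timepoints, a known rigid
#' pose difference, partial-volume blur and additive Gaussian noise. The
#' truth (lesion masks, transform, VOIs) is exact by construction and
#' recorded before blur/noise are applied.
#'
#' @param grid_shape voxel counts per axis.
#' @param spacing voxel size in mm (default 0.3 mm isotropic, the CBCT
#'   acquisition the pipeline targets).
#' @param bone_intensity,background_intensity mean gray values of bone and
#'   soft tissue; bone must exceed background (bimodal histogram assumption).
#' @param noise_sigma additive Gaussian noise SD (gray values), applied
#'   independently to both timepoints.
#' @param blur_sigma partial-volume Gaussian blur SD in mm, applied to both
#'   timepoints.
#' @param resorption_voxels,deposition_voxels exact true-voxel counts of the
#'   carved erosion lesion and of the added peripheral bone.
#' @param pose_offset rigid pose difference of the post-treatment scan:
#'   length-6 numeric, three rotations in degrees then three translations in
#'   mm.
#' @param intensity_drift gray-value offset added to the post-treatment
#'   volume (CBCT gray values are not reproducible across scans; default 0).
#' @param head_radii_mm semi-axes of the condylar head ellipsoid (mm).
#' @param supersample sub-voxel sampling factor per axis for anti-aliased
#'   (partial-volume) digitization of the continuous object; 1 gives crisp
#'   binary voxelization. A scanner integrates over the voxel aperture, so
#'   boundary voxels of real scans carry fractional intensities; crisp
#'   voxelization aliases the surface and is kept only as a degenerate
#'   option.
#' @param seed integer seed controlling all randomness of a generation call.
#' @return An object of class `cv_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(80L, 96L, 84L),
                         spacing = c(0.3, 0.3, 0.3),
                         bone_intensity = 1000,
                         background_intensity = 100,
                         noise_sigma = 0,
                         blur_sigma = 0,
                         resorption_voxels = 500L,
                         deposition_voxels = 200L,
                         pose_offset = c(0, 0, 0, 0, 0, 0),
                         intensity_drift = 0,
                         head_radii_mm = c(8, 10, 6),
                         supersample = 3L,
                         seed = 1L) {
  if (bone_intensity <= background_intensity)
    stop("phantom spec error: bone_intensity must exceed background_intensity",
         call. = FALSE)
  if (resorption_voxels < 0 || deposition_voxels < 0)
    stop("phantom spec error: lesion voxel counts must be >= 0", call. = FALSE)
  stopifnot(length(grid_shape) == 3, length(pose_offset) == 6)
  structure(
    list(grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
         bone_intensity = bone_intensity,
         background_intensity = background_intensity,
         noise_sigma = noise_sigma, blur_sigma = blur_sigma,
         resorption_voxels = as.integer(resorption_voxels),
         deposition_voxels = as.integer(deposition_voxels),
         pose_offset = as.numeric(pose_offset),
         intensity_drift = intensity_drift,
         head_radii_mm = as.numeric(head_radii_mm),
         supersample = as.integer(supersample),
         seed = as.integer(seed)),
    class = "cv_phantom_spec"
  )
}

#' Generate a synthetic pre/post condyle pair with known truth
#'
#' Builds the pre-treatment bone shape, carves `resorption_voxels` voxels
#' from the anterior-superior joint surface of the condylar head and adds
#' `deposition_voxels` voxels at the periphery of the resorption site (the
#' spatial pattern reported for osteoarthritic condyles), then applies the
#' rigid pose difference, partial-volume blur and noise to produce the
#' post-treatment volume. Lesion masks (in the pre-treatment frame), the
#' true post-to-pre transform and the head/validation VOI boxes are returned
#' as exact ground truth.
#'
#' @param spec a [phantom_spec()].
#' @param neck_height validation-VOI height in voxel slices recorded in the
#'   truth.
#' @return A list with `pre` and `post` ([voxel_volume()]s) and `truth`, a
#'   list with `resorption_mask`, `deposition_mask`, `true_transform`
#'   (mapping post-frame points to pre-frame points), `head_voi`,
#'   `validation_voi` and the `spec`.
#' @export
make_phantom_pair <- function(spec, neck_height = 20L) {
  stopifnot(inherits(spec, "cv_phantom_spec"))
  with_seed(spec$seed, {
    geomk <- phantom_geometry(spec)
    frac_pre <- bone_fraction(spec, offsets_mm(spec))
    solid <- frac_pre >= 1 - 1e-9   # fully-interior voxels
    empty <- frac_pre <= 1e-9       # fully-exterior voxels

    lesions <- carve_lesions(spec, geomk, frac_pre, solid, empty)

    bg <- spec$background_intensity
    amp <- spec$bone_intensity - bg
    sp <- spec$spacing
    pre <- voxel_volume(array(bg + amp * frac_pre, dim = spec$grid_shape), sp)

    center <- (spec$grid_shape - 1) / 2 * sp
    true_transform <- rigid_transform(spec$pose_offset[1:3],
                                      spec$pose_offset[4:6], center)
    if (any(spec$pose_offset != 0)) {
      # digitize the *moved* object directly: the post-frame voxel aperture
      # is sampled at sub-voxel points mapped rigidly into the pre frame,
      # where the continuous shape is evaluated and the voxel-cube lesions
      # are looked up — no interpolation of an already-digitized volume
      frac_post <- moved_fraction(spec, lesions, true_transform)
    } else {
      frac_post <- frac_pre
      frac_post[lesions$resorption] <- 0  # carved cubes become soft tissue
      frac_post[lesions$deposition] <- 1  # deposited cubes become bone
    }
    post <- voxel_volume(array(bg + amp * frac_post, dim = spec$grid_shape), sp)
    if (spec$blur_sigma > 0) {
      pre <- gaussian_blur_mm(pre, spec$blur_sigma)
      post <- gaussian_blur_mm(post, spec$blur_sigma)
    }
    if (spec$intensity_drift != 0)
      post <- voxel_volume(post$data + spec$intensity_drift, sp)
    if (spec$noise_sigma > 0) {
      pre <- voxel_volume(
        pre$data + array(stats::rnorm(length(pre$data), 0, spec$noise_sigma),
                         dim = dim(pre$data)), sp)
      post <- voxel_volume(
        post$data + array(stats::rnorm(length(post$data), 0, spec$noise_sigma),
                          dim = dim(post$data)), sp)
    }

    vois <- truth_vois(geomk, spec, neck_height, lesions)
    truth <- list(
      resorption_mask = binary_mask(lesions$resorption, sp),
      deposition_mask = binary_mask(lesions$deposition, sp),
      true_transform = true_transform,
      head_voi = vois$head,
      validation_voi = vois$validation,
      spec = spec
    )
    list(pre = pre, post = post, truth = truth)
  })
}

# ---- internals -------------------------------------------------------------

# The condyle-like shape, in the fixed LPS frame (+z superior, +y posterior):
# a cuboid ramus at the bottom, an elliptic-cylinder neck, an ellipsoidal-cap
# head on top, and a disconnected cranial slab above. Proportions are fixed
# in mm so any spacing yields the same physical shape.
phantom_geometry <- function(spec) {
  coords <- voxel_center_coords(spec)
  shape <- phantom_shape(spec, coords$X, coords$Y, coords$Z)
  c(shape, list(coords = coords))
}

voxel_center_coords <- function(spec) {
  d <- spec$grid_shape
  sp <- spec$spacing
  x <- (seq_len(d[1]) - 1) * sp[1]
  y <- (seq_len(d[2]) - 1) * sp[2]
  z <- (seq_len(d[3]) - 1) * sp[3]
  list(
    X = array(rep(x, times = d[2] * d[3]), dim = d),
    Y = array(rep(rep(y, each = d[1]), times = d[3]), dim = d),
    Z = array(rep(z, each = d[1] * d[2]), dim = d)
  )
}

# membership predicates of the continuous phantom, evaluated at arbitrary
# pre-frame coordinates (mm) — this is what makes faithful digitization of
# the rigidly moved object possible
phantom_shape <- function(spec, X, Y, Z) {
  sp <- spec$spacing
  ext <- (spec$grid_shape - 1) * sp
  cx <- ext[1] / 2
  cy <- ext[2] / 2
  hr <- spec$head_radii_mm

  zc <- 14                                     # head base height (mm)
  ramus <- abs(X - cx) <= 6.6 & abs(Y - cy) <= 3 & Z >= 2 & Z < 8
  neck <- ((X - cx) / 4)^2 + ((Y - cy) / 5)^2 <= 1 & Z >= 8 & Z < zc
  head <- ((X - cx) / hr[1])^2 + ((Y - cy) / hr[2])^2 +
    ((Z - zc) / hr[3])^2 <= 1 & Z >= zc
  cranial <- abs(X - cx) <= 7.5 & abs(Y - cy) <= 5.4 &
    Z >= zc + hr[3] + 3 & Z < zc + hr[3] + 5

  list(mandible = ramus | neck | head, cranial = cranial, head = head,
       center = c(cx, cy, zc))
}

# one bone-membership pass (mandible + cranial as one solid)
solid_at <- function(spec, X, Y, Z) {
  s <- phantom_shape(spec, X, Y, Z)
  s$mandible | s$cranial
}

# sub-voxel aperture offsets (mm): centers of supersample^3 subcells
offsets_mm <- function(spec) {
  s <- spec$supersample
  o1 <- ((2 * seq_len(s) - 1) / (2 * s) - 0.5)
  as.matrix(expand.grid(x = o1 * spec$spacing[1], y = o1 * spec$spacing[2],
                        z = o1 * spec$spacing[3]))
}

# partial-volume bone fraction of each voxel of the (unmoved) object
bone_fraction <- function(spec, offs) {
  co <- voxel_center_coords(spec)
  acc <- array(0, spec$grid_shape)
  for (r in seq_len(nrow(offs))) {
    acc <- acc + solid_at(spec, co$X + offs[r, 1], co$Y + offs[r, 2],
                          co$Z + offs[r, 3])
  }
  acc / nrow(offs)
}

# partial-volume bone fraction of the lesioned object, digitized on the
# post-frame grid: aperture points map through the true post-to-pre rigid
# transform; lesions (voxel cubes in the pre frame) by nearest-voxel lookup
moved_fraction <- function(spec, lesions, true_transform) {
  d <- spec$grid_shape
  sp <- spec$spacing
  af <- transform_affine(true_transform)
  co <- voxel_center_coords(spec)
  mx <- af$A[1, 1] * co$X + af$A[1, 2] * co$Y + af$A[1, 3] * co$Z + af$b[1]
  my <- af$A[2, 1] * co$X + af$A[2, 2] * co$Y + af$A[2, 3] * co$Z + af$b[2]
  mz <- af$A[3, 1] * co$X + af$A[3, 2] * co$Y + af$A[3, 3] * co$Z + af$b[3]
  offs <- offsets_mm(spec)
  acc <- array(0, d)
  any_lesion <- any(lesions$resorption) || any(lesions$deposition)
  for (r in seq_len(nrow(offs))) {
    ro <- as.numeric(af$A %*% offs[r, ])  # aperture offset, rotated
    px <- mx + ro[1]; py <- my + ro[2]; pz <- mz + ro[3]
    memb <- solid_at(spec, px, py, pz)
    if (any_lesion) {
      ni <- round(px / sp[1]) + 1
      nj <- round(py / sp[2]) + 1
      nk <- round(pz / sp[3]) + 1
      inb <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
      lidx <- (ni[inb] - 1) + d[1] * ((nj[inb] - 1) + d[2] * (nk[inb] - 1)) + 1
      m2 <- memb[inb]
      m2[lesions$resorption[lidx]] <- FALSE
      m2[lesions$deposition[lidx]] <- TRUE
      memb[inb] <- m2
    }
    acc <- acc + memb
  }
  acc / nrow(offs)
}

carve_lesions <- function(spec, geomk, frac_pre, solid, empty) {
  d <- spec$grid_shape
  res <- array(FALSE, d)
  dep <- array(FALSE, d)
  n_res <- spec$resorption_voxels
  n_dep <- spec$deposition_voxels
  if (n_res == 0 && n_dep == 0) return(list(resorption = res, deposition = dep))

  head_solid <- geomk$head & solid
  head_n <- sum(head_solid)
  if (n_res >= head_n || n_dep >= head_n)
    stop("phantom spec error: lesion (", max(n_res, n_dep),
         " voxels) is not smaller than the condylar head (", head_n,
         " interior voxels)", call. = FALSE)

  # seed on the anterior-superior joint surface: direction (0, -sin 45, cos 45)
  # from the head base center, pushed to the ellipsoid boundary
  hr <- spec$head_radii_mm
  dirv <- c(0, -sin(pi / 4), cos(pi / 4))
  t_hit <- 1 / sqrt((dirv[2] / hr[2])^2 + (dirv[3] / hr[3])^2)
  seed_mm <- geomk$center + t_hit * dirv

  X <- geomk$coords$X; Y <- geomk$coords$Y; Z <- geomk$coords$Z
  if (n_res > 0) {
    # carve fully-interior head voxels nearest the surface seed: bone at any
    # sensible threshold before carving, soft tissue after
    idx <- which(head_solid)
    d2 <- (X[idx] - seed_mm[1])^2 + (Y[idx] - seed_mm[2])^2 + (Z[idx] - seed_mm[3])^2
    ord <- order(d2, idx)
    res[idx[ord[seq_len(n_res)]]] <- TRUE
  }
  if (n_dep > 0) {
    # deposited bone apposes in compact layers on the outer surface around
    # the pit rim (new bone grows on existing surfaces with real thickness;
    # a detached one-voxel shell would not be bone apposition)
    r_pit <- if (n_res > 0) {
      ridx <- which(res)
      sqrt(max((X[ridx] - seed_mm[1])^2 + (Y[ridx] - seed_mm[2])^2 +
                 (Z[ridx] - seed_mm[3])^2))
    } else 0
    # apposition support is the mandible only — never the cranial slab,
    # whose surface can be distance-competitive with the rim
    support <- (frac_pre >= 0.5) & dilate26(geomk$mandible) & !res
    remaining <- n_dep
    guard <- 0L
    while (remaining > 0 && guard < 64L) {
      guard <- guard + 1L
      cand <- which(dilate26(support | dep) & empty & !dep)
      if (length(cand) == 0)
        stop("phantom spec error: not enough surface voxels for ", n_dep,
             " deposition voxels", call. = FALSE)
      dist_seed <- sqrt((X[cand] - seed_mm[1])^2 + (Y[cand] - seed_mm[2])^2 +
                          (Z[cand] - seed_mm[3])^2)
      ord <- order(abs(dist_seed - r_pit), cand)
      take <- utils::head(cand[ord], remaining)
      dep[take] <- TRUE
      remaining <- n_dep - sum(dep)
    }
    if (remaining > 0)
      stop("phantom spec error: could not place ", n_dep,
           " deposition voxels", call. = FALSE)
  }
  list(resorption = res, deposition = dep)
}

# 26-neighborhood binary dilation by one voxel
dilate26 <- function(arr) {
  d <- dim(arr)
  out <- arr
  for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    src_i <- max(1, 1 - di):min(d[1], d[1] - di)
    src_j <- max(1, 1 - dj):min(d[2], d[2] - dj)
    src_k <- max(1, 1 - dk):min(d[3], d[3] - dk)
    out[src_i + di, src_j + dj, src_k + dk] <-
      out[src_i + di, src_j + dj, src_k + dk] | arr[src_i, src_j, src_k]
  }
  out
}

truth_vois <- function(geomk, spec, neck_height, lesions) {
  # the head region plus any apposed new bone defines the box to crop
  w <- which(geomk$head | lesions$deposition, arr.ind = TRUE)
  d <- spec$grid_shape
  lo_xy <- pmax(apply(w[, 1:2, drop = FALSE], 2, min) - 2L, 1L)
  hi_xy <- pmin(apply(w[, 1:2, drop = FALSE], 2, max) + 2L, d[1:2])
  z_lo <- max(min(which(apply(geomk$head, 3, any))) - 1L, 1L)  # into the neck
  z_hi <- min(max(w[, 3]) + 2L, d[3])
  head <- voi_box(c(lo_xy, z_lo), c(hi_xy + 1L, z_hi + 1L))
  validation <- voi_box(c(lo_xy, z_lo - neck_height), c(hi_xy + 1L, z_lo))
  list(head = head, validation = validation)
}

#' Write a phantom pair to disk
#'
#' Writes `pre.nrrd`, `post.nrrd`, the truth lesion masks and a JSON truth
#' sidecar (pose as rotations in degrees + translations in mm, lesion counts,
#' VOI boxes) into a directory.
#'
#' @param pair result of [make_phantom_pair()].
#' @param dir output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_phantom_pair <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(pair$pre, file.path(dir, "pre.nrrd"))
  write_volume(pair$post, file.path(dir, "post.nrrd"))
  write_volume(pair$truth$resorption_mask, file.path(dir, "truth_resorption.nrrd"))
  write_volume(pair$truth$deposition_mask, file.path(dir, "truth_deposition.nrrd"))
  tr <- pair$truth$true_transform
  jsonlite::write_json(
    list(
      rotation_deg = tr$rotation, translation_mm = tr$translation,
      center_mm = tr$center,
      resorption_voxels = voxel_count(pair$truth$resorption_mask),
      deposition_voxels = voxel_count(pair$truth$deposition_mask),
      head_voi = list(lower = pair$truth$head_voi$lower,
                      upper = pair$truth$head_voi$upper),
      validation_voi = list(lower = pair$truth$validation_voi$lower,
                            upper = pair$truth$validation_voi$upper)
    ),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
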