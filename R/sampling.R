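#' Patch sampling configuration
#'
#' Controls the two-stage patch cropping and augmentation strategy: 32 initial
#' crops of 64 voxels per edge per scan (one third centred on CEL voxels for
#' positive scans, the rest on WML voxels; all on WML voxels for negative
#' scans), followed by a random sub-crop to 48 voxels per edge, then optional
#' flips, axis-pair 90-degree rotations, a small random affine, and an additive
#' intensity shift drawn from [-0.25, 0.25] after z-score normalization.
#'
#' @param patches_per_scan Number of initial crops per scan.
#' @param initial_patch Edge length (voxels) of the first crop.
#' @param final_patch Edge length (voxels) of the random sub-crop.
#' @param positive_fraction Fraction of patches centred on CEL voxels for
#'   CEL-positive scans; the count is \code{round(positive_fraction *
#'   patches_per_scan)} (11 of 32 at the defaults).
#' @param intensity_shift Half-width of the uniform additive intensity shift.
#' @param flip,rot90,affine Logical flags enabling each augmentation family.
#' @param affine_max_rotation_deg Maximum rotation angle of the random affine.
#' @param affine_scale_range Length-2 multiplicative scale range.
#' @return An object of class \code{sampling_config}.
#' @export
sampling_config <- function(patches_per_scan = 32L,
                            initial_patch = 64L,
                            final_patch = 48L,
                            positive_fraction = 1 / 3,
                            intensity_shift = 0.25,
                            flip = TRUE, rot90 = TRUE, affine = TRUE,
                            affine_max_rotation_deg = 10,
                            affine_scale_range = c(0.9, 1.1)) {
  if (final_patch > initial_patch) {
    stop("final_patch must not exceed initial_patch", call. = FALSE)
  }
  if (positive_fraction < 0 || positive_fraction > 1) {
    stop("positive_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (patches_per_scan < 1) stop("patches_per_scan must be >= 1", call. = FALSE)
  structure(list(
    patches_per_scan = as.integer(patches_per_scan),
    initial_patch = as.integer(initial_patch),
    final_patch = as.integer(final_patch),
    positive_fraction = positive_fraction,
    intensity_shift = intensity_shift,
    flip = flip, rot90 = rot90, affine = affine,
    affine_max_rotation_deg = affine_max_rotation_deg,
    affine_scale_range = affine_scale_range
  ), class = "sampling_config")
}

#' Z-score normalize a volume over a brain mask
#'
#' Standardizes intensities to zero mean and unit standard deviation computed
#' over the mask voxels only (skull-stripped images have large zero
#' backgrounds that would otherwise corrupt the statistics); voxels outside
#' the mask are set to 0. Statistics are per volume and per channel, never
#' pooled across scans.
#'
#' @param volume Numeric 3D array.
#' @param brain_mask Binary mask of the same shape; defaults to the nonzero
#'   voxels of \code{volume}.
#' @return Normalized array of the same shape.
#' @export
zscore_normalize <- function(volume, brain_mask = NULL) {
  if (is.null(brain_mask)) {
    brain_mask <- array(as.numeric(volume != 0), dim = dim(volume))
  }
  assert_binary_mask(brain_mask, "brain_mask")
  assert_same_dim(volume, brain_mask, "volume and brain_mask")
  idx <- brain_mask == 1
  if (sum(idx) < 2) stop("brain_mask must contain at least 2 voxels", call. = FALSE)
  v <- volume[idx]
  s <- sd(v)
  if (s == 0) stop("volume is constant within the mask (zero variance)",
                   call. = FALSE)
  out <- array(0, dim = dim(volume))
  out[idx] <- (v - mean(v)) / s
  out
}

#' Sample patch centres from the lesion masks of a scan
#'
#' For CEL-positive scans, \code{round(positive_fraction * patches_per_scan)}
#' centres are drawn uniformly (with replacement) over CEL voxels and the rest
#' over WML voxels; for CEL-free scans all centres are drawn over WML voxels.
#' Drawing uniformly over voxels means larger lesions are sampled more often.
#'
#' @param bundle A \code{scan_bundle}.
#' @param config A [sampling_config()].
#' @return A list with \code{centers} (n x 3 matrix of 1-based voxel indices)
#'   and \code{center_kind} (character, \code{"cel_centered"} or
#'   \code{"wml_centered"}).
#' @export
sample_patch_centers <- function(bundle, config) {
  wml_vox <- mask_coords(bundle$wml_mask)
  if (nrow(wml_vox) == 0) {
    stop("no sampling support: the WML mask is empty", call. = FALSE)
  }
  has_cels <- sum(bundle$cel_mask) > 0
  n <- config$patches_per_scan
  n_pos <- if (has_cels) round(config$positive_fraction * n) else 0L
  kinds <- c(rep("cel_centered", n_pos), rep("wml_centered", n - n_pos))
  centers <- matrix(0L, nrow = n, ncol = 3)
  if (n_pos > 0) {
    cel_vox <- mask_coords(bundle$cel_mask)
    centers[seq_len(n_pos), ] <- cel_vox[sample.int(nrow(cel_vox), n_pos,
                                                    replace = TRUE), , drop = FALSE]
  }
  if (n - n_pos > 0) {
    centers[(n_pos + 1):n, ] <- wml_vox[sample.int(nrow(wml_vox), n - n_pos,
                                                   replace = TRUE), , drop = FALSE]
  }
  list(centers = centers, center_kind = kinds)
}

# Clamped 0-based crop origin for a window of `edge` centred at `center`
# (1-based voxel index; for even edges the centre voxel sits at local
# position edge/2).
#' @noRd
crop_origin <- function(center, edge, grid_shape) {
  pmin(pmax(center - 1L - (edge - 1L) %/% 2L, 0L), grid_shape - edge)
}

#' Extract a multi-channel patch around a centre voxel
#'
#' Crops a cubic block of \code{config$initial_patch} voxels per edge from the
#' three intensity channels (in t1_pre, t1_post, flair order), the CEL ground
#' truth and the WML mask. The window is centred on the given voxel and
#' clamped so it fits inside the grid; the realized 0-based origin is
#' recorded.
#'
#' @param bundle A \code{scan_bundle} (intensities should already be
#'   normalized for training use).
#' @param center Length-3 integer voxel index (1-based).
#' @param config A [sampling_config()].
#' @param center_kind Label recorded on the patch.
#' @param edge Edge length override (defaults to \code{config$initial_patch}).
#' @return A \code{cel_patch}: list with \code{channels} (edge^3 x 3 array),
#'   \code{gt}, \code{wml} (binary arrays), \code{origin} (0-based),
#'   \code{center_kind} and \code{is_positive} (TRUE iff gt contains a CEL
#'   voxel).
#' @export
extract_patch <- function(bundle, center, config,
                          center_kind = "wml_centered",
                          edge = config$initial_patch) {
  gs <- dim(bundle$wml_mask)
  if (any(center < 1L) || any(center > gs)) {
    stop("patch centre lies outside the grid", call. = FALSE)
  }
  org <- crop_origin(as.integer(center), edge, gs)
  ix <- (org[1] + 1):(org[1] + edge)
  iy <- (org[2] + 1):(org[2] + edge)
  iz <- (org[3] + 1):(org[3] + edge)
  ch <- array(0, dim = c(edge, edge, edge, 3))
  ch[, , , 1] <- bundle$t1_pre[ix, iy, iz]
  ch[, , , 2] <- bundle$t1_post[ix, iy, iz]
  ch[, , , 3] <- bundle$flair[ix, iy, iz]
  gt <- bundle$cel_mask[ix, iy, iz]
  structure(list(
    channels = ch,
    gt = gt,
    wml = bundle$wml_mask[ix, iy, iz],
    origin = org,
    center_kind = center_kind,
    is_positive = sum(gt) >= 1
  ), class = "cel_patch")
}

#' Random sub-crop of a patch
#'
#' Second cropping stage: a sub-block of \code{config$final_patch} voxels per
#' edge at an offset drawn uniformly from \code{[0, initial - final]} per
#' axis. The patch origin is updated and \code{is_positive} recomputed from
#' the cropped ground truth (a lesion fragment can fall outside the sub-crop).
#'
#' @param patch A \code{cel_patch} at the initial edge length.
#' @param config A [sampling_config()].
#' @param offset Optional fixed length-3 offset (0-based) overriding the draw.
#' @return A \code{cel_patch} at the final edge length.
#' @export
random_subcrop <- function(patch, config, offset = NULL) {
  e0 <- dim(patch$gt)[1]
  e1 <- config$final_patch
  if (e0 < e1) stop("patch is smaller than final_patch", call. = FALSE)
  if (is.null(offset)) {
    offset <- if (e0 == e1) c(0L, 0L, 0L) else
      sample.int(e0 - e1 + 1L, 3, replace = TRUE) - 1L
  }
  offset <- as.integer(offset)
  ix <- (offset[1] + 1):(offset[1] + e1)
  iy <- (offset[2] + 1):(offset[2] + e1)
  iz <- (offset[3] + 1):(offset[3] + e1)
  gt <- patch$gt[ix, iy, iz]
  structure(list(
    channels = patch$channels[ix, iy, iz, , drop = FALSE],
    gt = gt,
    wml = patch$wml[ix, iy, iz],
    origin = patch$origin + offset,
    center_kind = patch$center_kind,
    is_positive = sum(gt) >= 1
  ), class = "cel_patch")
}

# Rotate/scale a cubic multi-channel block about its centre with a random
# small affine; trilinear interpolation for channels, nearest for masks.
#' @noRd
apply_affine <- function(patch, max_rot_deg, scale_range) {
  e <- dim(patch$gt)[1]
  ang <- runif(1, -max_rot_deg, max_rot_deg) * pi / 180
  axis <- sample.int(3, 1)
  scl <- runif(3, scale_range[1], scale_range[2])
  ca <- cos(ang); sa <- sin(ang)
  R <- switch(axis,
    matrix(c(1, 0, 0, 0, ca, -sa, 0, sa, ca), 3, 3, byrow = TRUE),
    matrix(c(ca, 0, sa, 0, 1, 0, -sa, 0, ca), 3, 3, byrow = TRUE),
    matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE))
  A <- R %*% diag(scl)
  Ainv <- solve(A)
  ctr <- (e + 1) / 2
  g <- as.matrix(expand.grid(x = seq_len(e), y = seq_len(e), z = seq_len(e)))
  src <- sweep(g, 2, ctr) %*% t(Ainv)
  src <- sweep(src, 2, ctr, `+`)

  nn <- round(src)
  nn_ok <- nn[, 1] >= 1 & nn[, 1] <= e & nn[, 2] >= 1 & nn[, 2] <= e &
           nn[, 3] >= 1 & nn[, 3] <= e
  sample_nn <- function(vol) {
    out <- numeric(nrow(nn))
    out[nn_ok] <- vol[nn[nn_ok, , drop = FALSE]]
    array(out, dim = c(e, e, e))
  }

  f0 <- floor(src)
  w <- src - f0
  sample_tri <- function(vol) {
    acc <- numeric(nrow(src))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      cx <- f0[, 1] + dx; cy <- f0[, 2] + dy; cz <- f0[, 3] + dz
      wt <- (dx * w[, 1] + (1 - dx) * (1 - w[, 1])) *
            (dy * w[, 2] + (1 - dy) * (1 - w[, 2])) *
            (dz * w[, 3] + (1 - dz) * (1 - w[, 3]))
      ok <- cx >= 1 & cx <= e & cy >= 1 & cy <= e & cz >= 1 & cz <= e & wt > 0
      if (any(ok)) {
        acc[ok] <- acc[ok] + wt[ok] * vol[cbind(cx[ok], cy[ok], cz[ok])]
      }
    }
    array(acc, dim = c(e, e, e))
  }

  for (c in seq_len(dim(patch$channels)[4])) {
    patch$channels[, , , c] <- sample_tri(patch$channels[, , , c])
  }
  patch$gt <- sample_nn(patch$gt)
  patch$wml <- sample_nn(patch$wml)
  patch
}

#' Flip a patch along one axis
#'
#' Deterministic mirror flip applied voxel-identically to channels, ground
#' truth and WML mask. Applying the same flip twice is the identity.
#'
#' @param patch A \code{cel_patch} (cubic).
#' @param axis Axis index (1, 2 or 3).
#' @return The flipped \code{cel_patch}.
#' @export
flip_patch <- function(patch, axis) {
  e <- dim(patch$gt)[1]
  idx <- rev(seq_len(e))
  f3 <- function(a) switch(axis, a[idx, , , drop = FALSE],
                           a[, idx, , drop = FALSE], a[, , idx, drop = FALSE])
  patch$channels <- switch(axis, patch$channels[idx, , , , drop = FALSE],
                           patch$channels[, idx, , , drop = FALSE],
                           patch$channels[, , idx, , drop = FALSE])
  patch$gt <- f3(patch$gt)
  patch$wml <- f3(patch$wml)
  patch
}

#' Rotate a patch by multiples of 90 degrees in an axis plane
#'
#' Deterministic rotation applied voxel-identically to channels, ground truth
#' and WML mask; four applications are the identity.
#'
#' @param patch A \code{cel_patch} (cubic).
#' @param axes Length-2 integer vector, the axis pair spanning the rotation
#'   plane.
#' @param k Number of quarter turns.
#' @return The rotated \code{cel_patch}.
#' @export
rot90_patch <- function(patch, axes = c(1, 2), k = 1) {
  axes <- sort(as.integer(axes))
  k <- as.integer(k) %% 4L
  if (k == 0L) return(patch)
  e <- dim(patch$gt)[1]
  idx <- rev(seq_len(e))
  perm3 <- seq_len(3); perm3[axes] <- rev(axes)
  rot1 <- function(a) {
    b <- aperm(a, perm3)
    switch(axes[1], b[idx, , , drop = FALSE], b[, idx, , drop = FALSE],
           b[, , idx, drop = FALSE])
  }
  rot14 <- function(a) {
    b <- aperm(a, c(perm3, 4))
    switch(axes[1], b[idx, , , , drop = FALSE], b[, idx, , , drop = FALSE],
           b[, , idx, , drop = FALSE])
  }
  for (i in seq_len(k)) {
    patch$channels <- rot14(patch$channels)
    patch$gt <- rot1(patch$gt)
    patch$wml <- rot1(patch$wml)
  }
  patch
}

#' Augment a patch
#'
#' Applies, in order: random flips per axis, a random axis-pair 90-degree
#' rotation, a small random affine (rotation up to 10 degrees, per-axis scale
#' 0.9-1.1, trilinear for channels and nearest-neighbour for masks so they
#' stay binary), and an additive intensity shift drawn uniformly from
#' \code{[-intensity_shift, intensity_shift]} applied to the channels only.
#' Spatial transforms are applied voxel-identically to channels, ground truth
#' and WML mask; \code{is_positive} is recomputed afterwards.
#'
#' @param patch A \code{cel_patch} (cubic).
#' @param config A [sampling_config()].
#' @return The augmented \code{cel_patch}.
#' @export
augment_patch <- function(patch, config) {
  if (isTRUE(config$flip)) {
    for (axis in 1:3) {
      if (runif(1) < 0.5) patch <- flip_patch(patch, axis)
    }
  }
  if (isTRUE(config$rot90)) {
    k <- sample(0:3, 1)
    ax <- sort(sample.int(3, 2))
    patch <- rot90_patch(patch, ax, k)
  }
  if (isTRUE(config$affine)) {
    patch <- apply_affine(patch, config$affine_max_rotation_deg,
                          config$affine_scale_range)
  }
  if (config$intensity_shift > 0) {
    patch$channels <- patch$channels +
      runif(1, -config$intensity_shift, config$intensity_shift)
  }
  patch$is_positive <- sum(patch$gt) >= 1
  patch
}

#' Normalize the intensity channels of a bundle
#'
#' Applies [zscore_normalize()] to each of the three channels over the brain
#' mask and returns a new bundle.
#'
#' @param bundle A \code{scan_bundle}.
#' @return The bundle with normalized \code{t1_pre}, \code{t1_post},
#'   \code{flair}.
#' @export
normalize_bundle <- function(bundle) {
  bm <- bundle$brain_mask
  if (is.null(bm)) bm <- array(as.numeric(bundle$t1_pre != 0),
                               dim = dim(bundle$t1_pre))
  bundle$t1_pre <- zscore_normalize(bundle$t1_pre, bm)
  bundle$t1_post <- zscore_normalize(bundle$t1_post, bm)
  bundle$flair <- zscore_normalize(bundle$flair, bm)
  bundle
}

#' Sample, crop and augment the training patches of one scan
#'
#' Full training-time sampling for one (already normalized) scan: draw patch
#' centres, extract initial crops, random sub-crop to the final edge, then
#' augment.
#'
#' @param bundle A normalized \code{scan_bundle}.
#' @param config A [sampling_config()].
#' @param augment Logical; apply [augment_patch()].
#' @return List of \code{cel_patch} objects at the final edge length.
#' @export
sample_training_patches <- function(bundle, config, augment = TRUE) {
  cs <- sample_patch_centers(bundle, config)
  lapply(seq_len(nrow(cs$centers)), function(i) {
    p <- extract_patch(bundle, cs$centers[i, ], config,
                       center_kind = cs$center_kind[i])
    p <- random_subcrop(p, config)
    if (augment) p <- augment_patch(p, config)
    p
  })
}
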