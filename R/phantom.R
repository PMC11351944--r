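#' Configuration for the synthetic multi-contrast brain phantom
#'
#' Parameters controlling the phantom generator. The defaults emulate the
#' statistical structure of a clinical MS cohort: roughly 56% of scans carry
#' at least one contrast-enhancing lesion (CEL), positive scans carry 3 CELs
#' on average, and lesion volumes follow a right-skewed lognormal with mean
#' around 136 mm^3, truncated below at 3 mm^3 (3 voxels at 1 mm isotropic).
#'
#' @param grid_shape Integer vector of length 3, voxels per axis. Each axis
#'   must be at least 64 so a full-size training patch fits.
#' @param voxel_size_mm Isotropic voxel spacing in mm.
#' @param n_wml Number of white-matter-lesion (WML) components per scan.
#' @param wml_volume_range_mm3 Length-2 numeric, min/max WML component volume.
#' @param p_scan_has_cels Probability that a scan is CEL-positive.
#' @param cel_count_mean Mean number of CELs per positive scan (the count is
#'   drawn as 1 + Poisson(cel_count_mean - 1) so positives have at least one).
#' @param cel_volume_lognormal_params Named or unnamed length-2 numeric
#'   (meanlog, sdlog) of the lesion-volume lognormal in mm^3.
#' @param min_cel_volume_mm3 Smallest generated lesion volume (>= 3).
#' @param contrast_levels Numeric matrix of per-tissue intensity means with
#'   rows \code{c("tissue", "wml", "cel", "confounder")} and columns
#'   \code{c("t1_pre", "t1_post", "flair")}.
#' @param noise_sigma Standard deviation of additive Gaussian noise.
#' @param n_confounders Number of vessel-like hyperintense tubes placed
#'   outside the WML mask on post-contrast T1.
#' @param p_ring Probability that a CEL above 50 mm^3 is carved as a
#'   hollow shell (ring-enhancing) rather than a nodular blob.
#' @param seed Optional integer seed stored in the config; used by
#'   [generate_scan()] and [generate_cohort()] when no explicit seed is given.
#'
#' @return An object of class \code{phantom_config}.
#' @export
phantom_config <- function(grid_shape = c(96L, 96L, 96L),
                           voxel_size_mm = 1,
                           n_wml = 6L,
                           wml_volume_range_mm3 = c(150, 1500),
                           p_scan_has_cels = 0.56,
                           cel_count_mean = 3,
                           cel_volume_lognormal_params = c(meanlog = 4.07, sdlog = 1.3),
                           min_cel_volume_mm3 = 3,
                           contrast_levels = default_contrast_levels(),
                           noise_sigma = 5,
                           n_confounders = 2L,
                           p_ring = 0,
                           seed = NULL) {
  grid_shape <- as.integer(rep(grid_shape, length.out = 3))
  if (any(grid_shape < 64L)) {
    stop("grid_shape must be at least 64 per axis to hold a training patch",
         call. = FALSE)
  }
  if (min_cel_volume_mm3 < 3) {
    stop("min_cel_volume_mm3 must be at least 3", call. = FALSE)
  }
  if (p_scan_has_cels < 0 || p_scan_has_cels > 1) {
    stop("p_scan_has_cels must lie in [0, 1]", call. = FALSE)
  }
  if (n_wml < 1 || cel_count_mean < 1 || n_confounders < 0) {
    stop("n_wml and cel_count_mean must be >= 1, n_confounders >= 0",
         call. = FALSE)
  }
  stopifnot(length(wml_volume_range_mm3) == 2,
            wml_volume_range_mm3[1] > 0,
            diff(wml_volume_range_mm3) >= 0,
            noise_sigma >= 0, p_ring >= 0, p_ring <= 1)
  structure(list(
    grid_shape = grid_shape,
    voxel_size_mm = voxel_size_mm,
    n_wml = as.integer(n_wml),
    wml_volume_range_mm3 = wml_volume_range_mm3,
    p_scan_has_cels = p_scan_has_cels,
    cel_count_mean = cel_count_mean,
    cel_volume_lognormal_params = unname(cel_volume_lognormal_params),
    min_cel_volume_mm3 = min_cel_volume_mm3,
    contrast_levels = contrast_levels,
    noise_sigma = noise_sigma,
    n_confounders = as.integer(n_confounders),
    p_ring = p_ring,
    seed = seed
  ), class = "phantom_config")
}

#' Default tissue intensity means for the phantom
#'
#' Rows are tissue classes, columns the three MRI channels. CELs enhance on
#' post-gadolinium T1 only; WMLs (and the CELs inside them) are hyperintense
#' on FLAIR; vessel-like confounders enhance on post-contrast T1 but are
#' FLAIR-isointense and lie outside the WML mask.
#'
#' @return A 4 x 3 numeric matrix.
#' @export
default_contrast_levels <- function() {
  m <- rbind(
    tissue     = c(100, 100, 100),
    wml        = c(85,  85,  170),
    cel        = c(85,  160, 170),
    confounder = c(100, 160, 100)
  )
  colnames(m) <- c("t1_pre", "t1_post", "flair")
  m
}

# Binary ellipsoid mask on the grid: centre (1-based), semi-axes in voxels.
#' @noRd
ellipsoid_mask <- function(grid_shape, centre, semi_axes) {
  ax <- seq_len(grid_shape[1]); ay <- seq_len(grid_shape[2]); az <- seq_len(grid_shape[3])
  dx2 <- ((ax - centre[1]) / semi_axes[1])^2
  dy2 <- ((ay - centre[2]) / semi_axes[2])^2
  dz2 <- ((az - centre[3]) / semi_axes[3])^2
  d <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  array(as.numeric(d <= 1), dim = grid_shape)
}

# Carve a quasi-ellipsoidal blob of exactly n_vox voxels centred at `centre`,
# restricted to `allowed` (binary). Voxels are taken nearest-first under a
# randomly scaled anisotropic metric; a hollow shell is carved when ring=TRUE.
#' @noRd
carve_blob <- function(grid_shape, centre, n_vox, allowed, ring = FALSE) {
  r0 <- max(2, ceiling((3 * n_vox / (4 * pi))^(1 / 3)))
  scales <- runif(3, 0.7, 1.4)
  r <- r0 + 2L
  repeat {
    lo <- pmax(centre - 3L * r, 1L)
    hi <- pmin(centre + 3L * r, grid_shape)
    gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
    dx2 <- ((gx - centre[1]) / scales[1])^2
    dy2 <- ((gy - centre[2]) / scales[2])^2
    dz2 <- ((gz - centre[3]) / scales[3])^2
    d <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    ok <- allowed[gx, gy, gz, drop = FALSE] == 1
    cand <- which(ok & d <= r^2, arr.ind = TRUE)
    if (nrow(cand) >= n_vox || r > max(grid_shape)) break
    r <- r + 2L
  }
  if (nrow(cand) < n_vox) n_vox <- nrow(cand)
  dv <- d[cbind(cand[, 1], cand[, 2], cand[, 3])]
  ord <- order(dv)
  if (ring && n_vox >= 20) {
    # shell: drop the innermost ~1/3 of voxels, keep the next n_vox
    core <- max(1L, floor(n_vox / 3))
    take <- ord[seq(core + 1L, min(core + n_vox, length(ord)))]
    if (length(take) < n_vox) take <- ord[seq_len(n_vox)]
  } else {
    take <- ord[seq_len(n_vox)]
  }
  sel <- cand[take, , drop = FALSE]
  cbind(sel[, 1] + lo[1] - 1L, sel[, 2] + lo[2] - 1L, sel[, 3] + lo[3] - 1L)
}

# Dilate a voxel coordinate set by one voxel (26-neighbourhood), clipped to grid.
#' @noRd
dilate_coords <- function(coords, grid_shape) {
  off <- rbind(c(0, 0, 0), neighbour_offsets(26L))
  out <- do.call(rbind, lapply(seq_len(nrow(off)), function(i) {
    sweep(coords, 2, off[i, ], `+`)
  }))
  out <- out[out[, 1] >= 1 & out[, 2] >= 1 & out[, 3] >= 1 &
             out[, 1] <= grid_shape[1] & out[, 2] <= grid_shape[2] &
             out[, 3] <= grid_shape[3], , drop = FALSE]
  unique(out)
}

# Draw one truncated-lognormal lesion volume (mm^3).
#' @noRd
draw_cel_volume <- function(config) {
  p <- config$cel_volume_lognormal_params
  for (i in 1:50) {
    v <- rlnorm(1, meanlog = p[1], sdlog = p[2])
    if (v >= config$min_cel_volume_mm3) return(v)
  }
  config$min_cel_volume_mm3
}

#' Generate one synthetic scan bundle
#'
#' Builds a skull-stripped, co-registered triplet of volumes (T1 pre- and
#' post-gadolinium, FLAIR) plus a WML mask and a CEL ground-truth mask on a
#' common isotropic grid. CELs are carved strictly inside WML components;
#' vessel-like confounder tubes are hyperintense on post-contrast T1 but never
#' intersect the WML mask, so only WML-overlap filtering can reject them.
#'
#' @param config A [phantom_config()].
#' @param seed Optional integer seed; falls back to \code{config$seed}. When
#'   both are NULL the current RNG state is used.
#' @param patient_id,scan_id Identifiers stored in the bundle.
#' @param force_positive Logical; when TRUE the scan always receives CELs.
#'
#' @return A \code{scan_bundle}: list with elements \code{t1_pre},
#'   \code{t1_post}, \code{flair} (numeric 3D arrays), \code{wml_mask},
#'   \code{cel_mask} (binary 3D arrays), \code{brain_mask}, \code{patient_id},
#'   \code{scan_id}, \code{voxel_size_mm}.
#' @export
generate_scan <- function(config, seed = NULL, patient_id = "P001",
                          scan_id = "S001", force_positive = FALSE) {
  stopifnot(inherits(config, "phantom_config"))
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  gs <- config$grid_shape
  centre <- (gs + 1) / 2
  brain <- ellipsoid_mask(gs, centre, 0.44 * gs)

  # candidate WML centres: interior of the brain, clear of its surface
  core <- ellipsoid_mask(gs, centre, 0.34 * gs)
  core_coords <- mask_coords(core)

  wml <- array(0, gs)
  vox_mm3 <- config$voxel_size_mm^3
  for (i in seq_len(config$n_wml)) {
    v <- runif(1, config$wml_volume_range_mm3[1], config$wml_volume_range_mm3[2])
    n_vox <- max(10L, round(v / vox_mm3))
    ctr <- core_coords[sample.int(nrow(core_coords), 1), ]
    vox <- carve_blob(gs, ctr, n_vox, brain)
    wml[vox] <- 1
  }

  cel <- array(0, gs)
  positive <- force_positive || (runif(1) < config$p_scan_has_cels)
  if (positive) {
    n_cels <- 1L + rpois(1, max(0, config$cel_count_mean - 1))
    wml_comps <- label_components(wml, connectivity = 26L)
    comp_sizes <- vapply(wml_comps$components, function(co) nrow(co$voxels), 0)
    for (j in seq_len(n_cels)) {
      v <- draw_cel_volume(config)
      n_vox <- max(round(config$min_cel_volume_mm3 / vox_mm3), round(v / vox_mm3))
      ci <- sample.int(length(comp_sizes), 1, prob = comp_sizes)
      comp_vox <- wml_comps$components[[ci]]$voxels
      # keep new lesions separated from existing ones so components stay distinct
      allowed <- brain
      if (sum(cel) > 0) {
        excl <- dilate_coords(dilate_coords(mask_coords(cel), gs), gs)
        allowed[excl] <- 0
      }
      free <- which(allowed[comp_vox] == 1)
      if (length(free) == 0) next
      ctr_xyz <- comp_vox[free[sample.int(length(free), 1)], ]
      ring <- config$p_ring > 0 && v > 50 && runif(1) < config$p_ring
      vox <- carve_blob(gs, ctr_xyz, n_vox, allowed, ring = ring)
      cel[vox] <- 1
      # guarantee cel_mask subset of wml_mask, with a one-voxel WML rim
      wml[dilate_coords(vox, gs)] <- 1
    }
  }

  conf <- array(0, gs)
  if (config$n_confounders > 0) {
    wml_excl <- wml
    if (sum(wml) > 0) wml_excl[dilate_coords(mask_coords(wml), gs)] <- 1
    brain_coords <- mask_coords(core)
    for (i in seq_len(config$n_confounders)) {
      p0 <- brain_coords[sample.int(nrow(brain_coords), 1), ]
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      len <- runif(1, 20, 35)
      ts <- seq(0, len, by = 0.5)
      pts <- unique(round(t(outer(dir, ts) + p0)))
      pts <- pts[pts[, 1] >= 2 & pts[, 2] >= 2 & pts[, 3] >= 2 &
                 pts[, 1] <= gs[1] - 1 & pts[, 2] <= gs[2] - 1 &
                 pts[, 3] <= gs[3] - 1, , drop = FALSE]
      if (nrow(pts) == 0) next
      tube <- dilate_coords(pts, gs)          # radius ~2 voxels
      tube <- tube[brain[tube] == 1 & wml_excl[tube] == 0, , drop = FALSE]
      conf[tube] <- 1
    }
  }

  cl <- config$contrast_levels
  vols <- lapply(colnames(cl), function(ch) {
    v <- brain * cl["tissue", ch]
    v[wml == 1] <- cl["wml", ch]
    v[cel == 1] <- cl["cel", ch]
    v[conf == 1] <- cl["confounder", ch]
    if (config$noise_sigma > 0) {
      v <- v + rnorm(length(v), sd = config$noise_sigma) * brain
    }
    v * brain
  })
  names(vols) <- colnames(cl)

  structure(list(
    t1_pre = vols$t1_pre, t1_post = vols$t1_post, flair = vols$flair,
    wml_mask = wml, cel_mask = cel, brain_mask = brain,
    confounder_mask = conf,
    patient_id = patient_id, scan_id = scan_id,
    voxel_size_mm = config$voxel_size_mm
  ), class = "scan_bundle")
}

#' Generate a cohort of synthetic scans
#'
#' Assigns \code{n_scans} scans to \code{n_patients} patients (every patient
#' has at least one scan; the remainder are distributed at random, so some
#' patients own multiple scans, as in longitudinal MS cohorts) and generates
#' one bundle per scan.
#'
#' @inheritParams generate_scan
#' @param n_scans Number of scans (>= 1).
#' @param n_patients Number of patients (<= n_scans).
#' @return List of \code{scan_bundle} objects.
#' @export
generate_cohort <- function(config, n_scans, n_patients = n_scans, seed = NULL) {
  if (n_scans < 1) stop("n_scans must be >= 1", call. = FALSE)
  if (n_patients > n_scans) stop("n_patients must be <= n_scans", call. = FALSE)
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  owner <- c(seq_len(n_patients),
             if (n_scans > n_patients)
               sample.int(n_patients, n_scans - n_patients, replace = TRUE))
  owner <- sort(owner)
  lapply(seq_len(n_scans), function(i) {
    generate_scan(config, seed = NULL,
                  patient_id = sprintf("P%03d", owner[i]),
                  scan_id = sprintf("S%03d", i))
  })
}

#' Summarise a cohort of scans
#'
#' Computes the composition statistics of a cohort: patients, scans, positive
#' and negative scans, total CEL count, mean CELs per positive scan and per
#' scan overall, and mean CEL volume in mm^3 (NA when the cohort has no CELs).
#'
#' @param x A list of \code{scan_bundle} objects, or a manifest
#'   \code{data.frame} with columns \code{patient_id}, \code{scan_id},
#'   \code{n_cels} and optionally \code{cel_volume_mm3} (summed per scan).
#' @return A one-row \code{data.frame} of summary statistics.
#' @export
cohort_summary <- function(x) {
  if (is.data.frame(x)) {
    man <- x
  } else {
    if (!is.list(x) || length(x) == 0) {
      stop("cohort_summary() needs a non-empty list of scan bundles or a manifest",
           call. = FALSE)
    }
    man <- cohort_manifest(x)
  }
  if (nrow(man) == 0) stop("empty cohort", call. = FALSE)
  pos <- man$n_cels > 0
  total_cels <- sum(man$n_cels)
  mean_vol <- if ("cel_volume_mm3" %in% names(man) && total_cels > 0) {
    sum(man$cel_volume_mm3) / total_cels
  } else {
    NA_real_
  }
  data.frame(
    n_patients = length(unique(man$patient_id)),
    n_scans = nrow(man),
    n_scans_with_cels = sum(pos),
    n_scans_without_cels = sum(!pos),
    n_cels_total = total_cels,
    mean_cels_per_positive_scan = if (any(pos)) total_cels / sum(pos) else NA_real_,
    mean_cels_per_scan = total_cels / nrow(man),
    mean_cel_volume_mm3 = mean_vol
  )
}

#' Build a per-scan manifest from a list of bundles
#'
#' @param bundles List of \code{scan_bundle} objects.
#' @return A \code{data.frame} with one row per scan: \code{patient_id},
#'   \code{scan_id}, \code{has_cels}, \code{n_cels}, \code{cel_volume_mm3}.
#' @export
cohort_manifest <- function(bundles) {
  rows <- lapply(bundles, function(b) {
    ls <- label_components(b$cel_mask, connectivity = 26L)
    n <- length(ls$components)
    vol <- sum(b$cel_mask) * b$voxel_size_mm^3
    data.frame(patient_id = b$patient_id, scan_id = b$scan_id,
               has_cels = n > 0, n_cels = n, cel_volume_mm3 = vol)
  })
  do.call(rbind, rows)
}

#' Write a scan bundle as NIfTI files
#'
#' Writes five gzipped NIfTI volumes with a shared RAS affine at the bundle's
#' isotropic spacing: \code{<scan_id>_t1.nii.gz}, \code{_t1c}, \code{_flair},
#' \code{_wml}, \code{_gt}.
#'
#' @param bundle A \code{scan_bundle}.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the five file paths.
#' @export
write_scan_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vols <- list(t1 = bundle$t1_pre, t1c = bundle$t1_post, flair = bundle$flair,
               wml = bundle$wml_mask, gt = bundle$cel_mask)
  paths <- vapply(names(vols), function(nm) {
    path <- file.path(dir, sprintf("%s_%s.nii.gz", bundle$scan_id, nm))
    img <- RNifti::asNifti(vols[[nm]],
                           pixdim = rep(bundle$voxel_size_mm, 3))
    RNifti::writeNifti(img, path)
    path
  }, character(1))
  invisible(paths)
}

#' Read a scan bundle from NIfTI files
#'
#' Counterpart of [write_scan_bundle()].
#'
#' @param dir Directory holding the five NIfTI files.
#' @param scan_id Scan identifier (file prefix).
#' @param patient_id Patient identifier to record in the bundle.
#' @return A \code{scan_bundle}.
#' @export
read_scan_bundle <- function(dir, scan_id, patient_id = scan_id) {
  rd <- function(sfx) {
    path <- file.path(dir, sprintf("%s_%s.nii.gz", scan_id, sfx))
    if (!file.exists(path)) stop("missing input file: ", path, call. = FALSE)
    arr <- as.array(RNifti::readNifti(path))
    array(as.numeric(arr), dim = dim(arr))
  }
  t1 <- rd("t1"); t1c <- rd("t1c"); fl <- rd("flair")
  wml <- rd("wml"); gt <- rd("gt")
  assert_binary_mask(wml, "wml"); assert_binary_mask(gt, "gt")
  structure(list(
    t1_pre = t1, t1_post = t1c, flair = fl,
    wml_mask = wml, cel_mask = gt,
    brain_mask = array(as.numeric(t1 != 0), dim = dim(t1)),
    patient_id = patient_id, scan_id = scan_id, voxel_size_mm = 1
  ), class = "scan_bundle")
}
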