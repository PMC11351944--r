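#' Label connected components of a binary 3D mask
#'
#' Breadth-first labelling of maximal connected components under 6-, 18- or
#' 26-connectivity (26 by default, the common choice in MS lesion tooling).
#'
#' @param mask Binary 3D array.
#' @param connectivity One of 6, 18, 26.
#' @param voxel_size_mm Isotropic voxel spacing, used for volumes in mm^3.
#' @return A \code{lesion_set}: list with \code{components} (each a list with
#'   \code{label_id}, \code{voxels} (n x 3 matrix of 1-based voxel indices),
#'   \code{n_voxels}, \code{volume_mm3}, \code{wml_overlap_fraction}, NA until
#'   [filter_lesions()] or [match_lesions()] computes it), \code{grid_shape}
#'   and \code{voxel_size_mm}.
#' @export
label_components <- function(mask, connectivity = 26L, voxel_size_mm = 1) {
  if (length(dim(mask)) != 3) stop("mask must be a 3D array", call. = FALSE)
  assert_binary_mask(mask, "mask")
  gs <- dim(mask)
  d1 <- gs[1]; d12 <- gs[1] * gs[2]
  offs <- neighbour_offsets(as.integer(connectivity))
  labels <- integer(length(mask))
  fg <- which(mask == 1)
  comps <- list()
  lab <- 0L
  for (seed in fg) {
    if (labels[seed] > 0L) next
    lab <- lab + 1L
    labels[seed] <- lab
    frontier <- seed
    members <- seed
    while (length(frontier) > 0) {
      co <- arrayInd(frontier, gs)
      nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i) {
        sweep(co, 2, offs[i, ], `+`)
      }))
      ok <- nb[, 1] >= 1 & nb[, 1] <= gs[1] &
            nb[, 2] >= 1 & nb[, 2] <= gs[2] &
            nb[, 3] >= 1 & nb[, 3] <= gs[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique(nb[, 1] + (nb[, 2] - 1L) * d1 + (nb[, 3] - 1L) * d12)
      lin <- lin[mask[lin] == 1 & labels[lin] == 0L]
      labels[lin] <- lab
      members <- c(members, lin)
      frontier <- lin
    }
    comps[[lab]] <- list(
      label_id = lab,
      voxels = arrayInd(members, gs),
      n_voxels = length(members),
      volume_mm3 = length(members) * voxel_size_mm^3,
      wml_overlap_fraction = NA_real_
    )
  }
  structure(list(components = comps, grid_shape = gs,
                 voxel_size_mm = voxel_size_mm),
            class = "lesion_set")
}

#' Convert a lesion set back to a binary mask
#'
#' @param lesions A \code{lesion_set}.
#' @return Binary 3D array on the lesion set's grid.
#' @export
lesion_set_to_mask <- function(lesions) {
  stopifnot(inherits(lesions, "lesion_set"))
  m <- array(0, lesions$grid_shape)
  for (co in lesions$components) m[co$voxels] <- 1
  m
}

#' Filter predicted lesions by volume and WML overlap
#'
#' Applies the two rule-based exclusion criteria used on whole-image
#' predictions: components smaller than \code{min_voxels} voxels are removed,
#' and components whose fraction of voxels inside the WML mask is strictly
#' below \code{min_wml_fraction} are removed (a component overlapping exactly
#' 10% is kept). Vessel-like confounders, which never intersect the WML mask,
#' are removed by the overlap rule. The rules are conjunctive, so their order
#' is irrelevant, and the operation is idempotent.
#'
#' @param lesions A \code{lesion_set} of predicted components.
#' @param wml_mask Binary WML mask on the same grid.
#' @param min_voxels Minimum component size in voxels (default 3).
#' @param min_wml_fraction Minimum fraction of component voxels inside the
#'   WML mask (default 0.10).
#' @return A filtered \code{lesion_set}; surviving components carry their
#'   computed \code{wml_overlap_fraction}.
#' @export
filter_lesions <- function(lesions, wml_mask, min_voxels = 3,
                           min_wml_fraction = 0.10) {
  stopifnot(inherits(lesions, "lesion_set"))
  assert_binary_mask(wml_mask, "wml_mask")
  if (!identical(dim(wml_mask), as.integer(lesions$grid_shape)) &&
      !identical(dim(wml_mask), lesions$grid_shape)) {
    stop("wml_mask grid does not match the lesion set", call. = FALSE)
  }
  kept <- list()
  for (co in lesions$components) {
    frac <- mean(wml_mask[co$voxels] == 1)
    co$wml_overlap_fraction <- frac
    if (co$n_voxels >= min_voxels && frac >= min_wml_fraction) {
      co$label_id <- length(kept) + 1L
      kept[[length(kept) + 1L]] <- co
    }
  }
  structure(list(components = kept, grid_shape = lesions$grid_shape,
                 voxel_size_mm = lesions$voxel_size_mm),
            class = "lesion_set")
}

#' Postprocess a binary prediction volume
#'
#' Convenience wrapper: labels the prediction, applies [filter_lesions()] and
#' returns the cleaned binary mask.
#'
#' @param pred_mask Binary predicted CEL mask.
#' @param wml_mask Binary WML mask on the same grid.
#' @inheritParams filter_lesions
#' @param connectivity Component connectivity (6, 18 or 26).
#' @param voxel_size_mm Isotropic voxel spacing.
#' @return Binary 3D array after filtering.
#' @export
postprocess_prediction <- function(pred_mask, wml_mask, min_voxels = 3,
                                   min_wml_fraction = 0.10,
                                   connectivity = 26L, voxel_size_mm = 1) {
  assert_same_dim(pred_mask, wml_mask, "pred_mask and wml_mask")
  ls <- label_components(pred_mask, connectivity = connectivity,
                         voxel_size_mm = voxel_size_mm)
  lesion_set_to_mask(filter_lesions(ls, wml_mask, min_voxels, min_wml_fraction))
}
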