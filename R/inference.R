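#' Deterministic WML-covering patch grid
#'
#' Tiles the bounding box of the WML mask with cubic windows of edge
#' \code{edge} stepping \code{step} voxels (50% overlap by default), clamped
#' to the grid, and keeps only windows intersecting the mask. Every WML voxel
#' is covered by at least one retained window.
#'
#' @param wml_mask Binary 3D array.
#' @param edge Window edge length in voxels.
#' @param step Step between window origins (default \code{edge / 2}).
#' @return Integer matrix of 0-based window origins (n x 3); zero rows when
#'   the mask is empty.
#' @export
wml_patch_grid <- function(wml_mask, edge, step = edge %/% 2L) {
  assert_binary_mask(wml_mask, "wml_mask")
  gs <- dim(wml_mask)
  if (any(gs < edge)) stop("grid smaller than the inference window", call. = FALSE)
  co <- mask_coords(wml_mask)
  if (nrow(co) == 0) return(matrix(integer(0), 0, 3))
  lo <- apply(co, 2, min) - 1L  # 0-based bbox
  hi <- apply(co, 2, max) - 1L
  axis_origins <- function(a) {
    os <- seq(lo[a], hi[a], by = step)
    os <- pmin(os, gs[a] - edge)
    os <- pmax(os, 0L)
    # ensure the bbox end is covered
    if (max(os) + edge - 1L < hi[a]) os <- c(os, min(hi[a], gs[a] - edge))
    sort(unique(as.integer(os)))
  }
  g <- as.matrix(expand.grid(x = axis_origins(1), y = axis_origins(2),
                             z = axis_origins(3)))
  keep <- vapply(seq_len(nrow(g)), function(i) {
    o <- g[i, ]
    sum(wml_mask[(o[1] + 1):(o[1] + edge), (o[2] + 1):(o[2] + edge),
                 (o[3] + 1):(o[3] + edge)]) > 0
  }, logical(1))
  unname(g[keep, , drop = FALSE])
}

#' Reconstruct a whole-image mask from patch predictions
#'
#' Maps binarized patch predictions back to their origins; overlapping voxel
#' predictions are summed and values exceeding 1 clipped to 1 (equivalently,
#' a voxel-wise union), so the result is independent of patch order. Voxels
#' covered by no patch are 0.
#'
#' @param patch_preds List of binary (or probability, see \code{threshold})
#'   3D arrays.
#' @param origins Integer matrix (n x 3) of 0-based patch origins.
#' @param grid_shape Length-3 integer target shape.
#' @param threshold When non-NULL, each patch is binarized at this
#'   probability before summation.
#' @return Binary 3D array.
#' @export
reconstruct <- function(patch_preds, origins, grid_shape, threshold = NULL) {
  stopifnot(length(patch_preds) == nrow(origins))
  acc <- array(0, grid_shape)
  for (i in seq_along(patch_preds)) {
    p <- patch_preds[[i]]
    if (!is.null(threshold)) p <- (p >= threshold) * 1
    assert_binary_mask(p, sprintf("patch_preds[[%d]]", i))
    e <- dim(p)
    o <- origins[i, ]
    if (any(o < 0) || any(o + e > grid_shape)) {
      stop("patch origin out of bounds", call. = FALSE)
    }
    ix <- (o[1] + 1):(o[1] + e[1]); iy <- (o[2] + 1):(o[2] + e[2])
    iz <- (o[3] + 1):(o[3] + e[3])
    acc[ix, iy, iz] <- acc[ix, iy, iz] + p
  }
  (acc >= 1) * 1
}

#' Whole-scan inference guided by the WML mask
#'
#' Normalizes the scan exactly as in training, tiles the WML mask with
#' overlapping windows at the model's input edge, predicts each window,
#' binarizes at \code{threshold}, and reconstructs the whole-image mask by
#' sum-and-clip. Regions outside every window (in particular everything far
#' from WML) are 0. An empty WML mask yields an all-zero volume with a
#' warning, since by definition a CEL cannot exist outside white matter
#' lesions.
#'
#' @param model A \code{celseg_model}.
#' @param bundle A \code{scan_bundle} (raw intensities; normalization is
#'   applied internally).
#' @param edge Inference window edge (default 48, the training patch edge).
#' @param step Window step (default \code{edge / 2}).
#' @param threshold Binarization threshold (default 0.5).
#' @param normalized Set TRUE when \code{bundle} is already normalized.
#' @param mode \code{"union"} (default) binarizes each window at
#'   \code{threshold} and combines by sum-and-clip; \code{"average"}
#'   accumulates raw probabilities over overlapping windows and thresholds
#'   their per-voxel mean, which suppresses speckle from single dissenting
#'   windows.
#' @return Binary 3D array of predicted CEL voxels (pre-postprocessing).
#' @export
infer_scan <- function(model, bundle, edge = 48L, step = edge %/% 2L,
                       threshold = 0.5, normalized = FALSE,
                       mode = c("union", "average")) {
  mode <- match.arg(mode)
  if (!normalized) bundle <- normalize_bundle(bundle)
  origins <- wml_patch_grid(bundle$wml_mask, edge, step)
  gs <- dim(bundle$wml_mask)
  if (nrow(origins) == 0) {
    warning("empty WML mask: returning an all-zero prediction")
    return(array(0, gs))
  }
  preds <- lapply(seq_len(nrow(origins)), function(i) {
    o <- origins[i, ]
    ix <- (o[1] + 1):(o[1] + edge); iy <- (o[2] + 1):(o[2] + edge)
    iz <- (o[3] + 1):(o[3] + edge)
    x <- array(0, c(edge, edge, edge, 3))
    x[, , , 1] <- bundle$t1_pre[ix, iy, iz]
    x[, , , 2] <- bundle$t1_post[ix, iy, iz]
    x[, , , 3] <- bundle$flair[ix, iy, iz]
    unet_forward(model, x)$prob
  })
  if (mode == "union") {
    return(reconstruct(preds, origins, gs, threshold = threshold))
  }
  sum_map <- array(0, gs)
  count_map <- array(0, gs)
  for (i in seq_along(preds)) {
    o <- origins[i, ]
    ix <- (o[1] + 1):(o[1] + edge); iy <- (o[2] + 1):(o[2] + edge)
    iz <- (o[3] + 1):(o[3] + edge)
    sum_map[ix, iy, iz] <- sum_map[ix, iy, iz] + preds[[i]]
    count_map[ix, iy, iz] <- count_map[ix, iy, iz] + 1
  }
  covered <- count_map > 0
  out <- array(0, gs)
  out[covered] <- (sum_map[covered] / count_map[covered] >= threshold) * 1
  out
}
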