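#' Lesion-level matching of predicted against ground-truth components
#'
#' Under the default one-voxel-overlap criterion, a ground-truth component
#' with at least one overlapping predicted voxel is a true positive (TP); a
#' ground-truth component with no overlap is a false negative (FN); a
#' predicted component overlapping no ground-truth component is a false
#' positive (FP). A predicted component may support several ground-truth
#' components (each counts as its own TP) and is never an FP once it touches
#' any ground truth; two predicted components hitting one ground-truth lesion
#' still count as a single TP. The per-lesion dice score of each TP is
#' computed between the ground-truth component and the union of the predicted
#' components overlapping it. An IoU-threshold criterion is available as an
#' alternative matching mode.
#'
#' @param pred A \code{lesion_set} of (filtered) predicted components.
#' @param gt A \code{lesion_set} of ground-truth components on the same grid.
#' @param criterion \code{"overlap"} (default) or \code{"iou"}.
#' @param iou_threshold Minimum intersection-over-union for a TP under the
#'   \code{"iou"} criterion.
#' @return A \code{lesion_match}: list with \code{counts}
#'   (\code{n_tp}, \code{n_fp}, \code{n_fn}), \code{tp_pairs} (per matched
#'   ground-truth lesion: its index, volume, matched predicted component
#'   indices, per-lesion dice), \code{fp_components}, \code{fn_components}
#'   (indices into the input sets).
#' @export
match_lesions <- function(pred, gt, criterion = c("overlap", "iou"),
                          iou_threshold = 0.1) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(pred, "lesion_set"), inherits(gt, "lesion_set"))
  if (!identical(as.integer(pred$grid_shape), as.integer(gt$grid_shape))) {
    stop("pred and gt lesion sets are on different grids", call. = FALSE)
  }
  gs <- gt$grid_shape
  lin <- function(v) v[, 1] + (v[, 2] - 1L) * gs[1] + (v[, 3] - 1L) * gs[1] * gs[2]
  pred_lin <- lapply(pred$components, function(co) lin(co$voxels))
  gt_lin <- lapply(gt$components, function(co) lin(co$voxels))
  n_p <- length(pred_lin); n_g <- length(gt_lin)
  overlap <- matrix(0L, n_g, max(n_p, 1))
  for (gi in seq_len(n_g)) {
    for (pi in seq_len(n_p)) {
      ov <- length(intersect(gt_lin[[gi]], pred_lin[[pi]]))
      if (criterion == "iou" && ov > 0) {
        iou <- ov / length(union(gt_lin[[gi]], pred_lin[[pi]]))
        if (iou < iou_threshold) ov <- 0L
      }
      overlap[gi, pi] <- ov
    }
  }
  tp_pairs <- list()
  fn_components <- integer(0)
  matched_pred <- rep(FALSE, n_p)
  for (gi in seq_len(n_g)) {
    pis <- if (n_p > 0) which(overlap[gi, ] > 0) else integer(0)
    if (length(pis) == 0) {
      fn_components <- c(fn_components, gi)
      next
    }
    matched_pred[pis] <- TRUE
    union_pred <- unique(unlist(pred_lin[pis]))
    inter <- sum(union_pred %in% gt_lin[[gi]])
    dsc <- 2 * inter / (length(union_pred) + length(gt_lin[[gi]]))
    tp_pairs[[length(tp_pairs) + 1]] <- list(
      gt_index = gi,
      gt_volume_mm3 = gt$components[[gi]]$volume_mm3,
      pred_indices = pis,
      dsc = dsc
    )
  }
  fp_components <- which(!matched_pred)
  structure(list(
    counts = detection_counts(n_tp = length(tp_pairs),
                              n_fp = length(fp_components),
                              n_fn = length(fn_components)),
    tp_pairs = tp_pairs,
    fp_components = fp_components,
    fn_components = fn_components,
    pred = pred, gt = gt
  ), class = "lesion_match")
}

#' Lesion-level detection counts
#'
#' @param n_tp,n_fp,n_fn Non-negative lesion counts.
#' @return A \code{detection_counts} object.
#' @export
detection_counts <- function(n_tp = 0L, n_fp = 0L, n_fn = 0L) {
  stopifnot(n_tp >= 0, n_fp >= 0, n_fn >= 0)
  structure(list(n_tp = as.integer(n_tp), n_fp = as.integer(n_fp),
                 n_fn = as.integer(n_fn)), class = "detection_counts")
}

#' Lesion-level true positive rate
#'
#' \code{n_tp / (n_tp + n_fn)}: the fraction of ground-truth lesions that
#' were detected. Undefined (NA) when no ground-truth lesion exists.
#'
#' @param counts A [detection_counts()] (or a \code{lesion_match}).
#' @return Fraction in \code{[0, 1]}, or NA.
#' @export
true_positive_rate <- function(counts) {
  if (inherits(counts, "lesion_match")) counts <- counts$counts
  den <- counts$n_tp + counts$n_fn
  if (den == 0) return(NA_real_)
  counts$n_tp / den
}

#' Lesion-level false positive rate
#'
#' \code{n_fp / (n_tp + n_fp)}: the fraction of predicted lesions that are
#' spurious. Undefined (NA) when nothing was predicted.
#'
#' @param counts A [detection_counts()] (or a \code{lesion_match}).
#' @return Fraction in \code{[0, 1]}, or NA.
#' @export
false_positive_rate <- function(counts) {
  if (inherits(counts, "lesion_match")) counts <- counts$counts
  den <- counts$n_tp + counts$n_fp
  if (den == 0) return(NA_real_)
  counts$n_fp / den
}

#' Dice score coefficient between two binary masks
#'
#' Hard binary overlap \code{2 TP / (2 TP + FN + FP)} over voxels, with no
#' smoothing (the training-side soft counterpart is [dice_loss()]).
#' Undefined (NA) when both masks are empty.
#'
#' @param pred,gt Binary arrays on the same grid.
#' @return Fraction in \code{[0, 1]}, or NA.
#' @export
dice_coefficient <- function(pred, gt) {
  assert_binary_mask(pred, "pred"); assert_binary_mask(gt, "gt")
  assert_same_dim(pred, gt, "pred and gt")
  if (sum(pred) + sum(gt) == 0) return(NA_real_)
  tp <- sum(pred * gt)
  fn <- sum(gt * (1 - pred))
  fp <- sum(pred * (1 - gt))
  2 * tp / (2 * tp + fn + fp)
}

#' Whole-image dice score
#'
#' Voxel dice over the full grids of a filtered prediction against the ground
#' truth, computed only for images with at least one TP lesion; images with
#' ground-truth lesions but no TP are excluded (NA), not scored 0, so that
#' cohort means are over detected-lesion images only.
#'
#' @param pred_mask Binary filtered prediction.
#' @param gt_mask Binary ground truth on the same grid.
#' @param connectivity Component connectivity for TP determination.
#' @return Fraction in \code{[0, 1]}, or NA when the image has no TP lesion.
#' @export
whole_image_dsc <- function(pred_mask, gt_mask, connectivity = 26L) {
  assert_same_dim(pred_mask, gt_mask, "pred_mask and gt_mask")
  m <- match_lesions(label_components(pred_mask, connectivity),
                     label_components(gt_mask, connectivity))
  if (m$counts$n_tp == 0) return(NA_real_)
  dice_coefficient(pred_mask, gt_mask)
}

#' Mean dice over validation patches
#'
#' Patch-level dice convention: within each patch, predicted components that
#' do not overlap the patch's WML mask are deleted, but no minimum-volume
#' rule is applied (a patch may hold only a fragment of a lesion). A patch
#' contributes to the mean only if it has at least one TP lesion.
#'
#' @param pred_patches List of binary predicted patch masks.
#' @param gt_patches List of binary ground-truth patch masks.
#' @param wml_patches List of binary WML patch masks.
#' @param connectivity Component connectivity.
#' @return Mean dice over qualifying patches, or NA when none qualifies.
#' @export
patch_dsc <- function(pred_patches, gt_patches, wml_patches,
                      connectivity = 26L) {
  stopifnot(length(pred_patches) == length(gt_patches),
            length(pred_patches) == length(wml_patches))
  vals <- vapply(seq_along(pred_patches), function(i) {
    pred <- pred_patches[[i]]
    ls <- label_components(pred, connectivity)
    # WML-overlap rule only; no minimum volume within patches
    ls <- filter_lesions(ls, wml_patches[[i]], min_voxels = 1,
                         min_wml_fraction = .Machine$double.eps)
    pred <- lesion_set_to_mask(ls)
    m <- match_lesions(ls, label_components(gt_patches[[i]], connectivity))
    if (m$counts$n_tp == 0) return(NA_real_)
    dice_coefficient(pred, gt_patches[[i]])
  }, numeric(1))
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

#' Default lesion-volume strata (mm^3)
#'
#' Bins partitioning \code{[3, Inf)}: 3-10, 10-20, 20-30, 30-40, 40-50,
#' 50-100, 100-200, 200-300, >300.
#'
#' @return Data frame with \code{label}, \code{lo}, \code{hi}.
#' @export
volume_strata <- function() {
  lo <- c(3, 10, 20, 30, 40, 50, 100, 200, 300)
  hi <- c(10, 20, 30, 40, 50, 100, 200, 300, Inf)
  data.frame(label = c("3-10", "10-20", "20-30", "30-40", "40-50", "50-100",
                       "100-200", "200-300", ">300"),
             lo = lo, hi = hi)
}

#' Volume-stratified detection and segmentation report
#'
#' Tallies TP, FN and FP lesions and mean per-lesion dice per volume stratum.
#' TP and FN lesions are binned by their ground-truth volume; FP lesions by
#' their own volume. The \code{"All"} row aggregates the counts and averages
#' the per-lesion dice over every TP lesion.
#'
#' @param match A \code{lesion_match} from [match_lesions()].
#' @param strata Stratum definition as from [volume_strata()].
#' @param digits Decimal places for the reported mean dice (default 2).
#' @return Data frame with columns \code{volume_bin}, \code{n_tp},
#'   \code{n_fn}, \code{n_fp}, \code{mean_dsc}.
#' @export
stratify_by_volume <- function(match, strata = volume_strata(), digits = 2) {
  stopifnot(inherits(match, "lesion_match"))
  tp_vol <- vapply(match$tp_pairs, function(p) p$gt_volume_mm3, numeric(1))
  tp_dsc <- vapply(match$tp_pairs, function(p) p$dsc, numeric(1))
  fn_vol <- vapply(match$fn_components,
                   function(i) match$gt$components[[i]]$volume_mm3, numeric(1))
  fp_vol <- vapply(match$fp_components,
                   function(i) match$pred$components[[i]]$volume_mm3, numeric(1))
  stratify_vectors(tp_vol, tp_dsc, fn_vol, fp_vol, strata, digits)
}

# Shared binning engine for single-scan and pooled cohort reports.
#' @noRd
stratify_vectors <- function(tp_vol, tp_dsc, fn_vol, fp_vol,
                             strata = volume_strata(), digits = 2) {
  bin_of <- function(v) {
    i <- which(v >= strata$lo & v < strata$hi)
    if (length(i) == 0) NA_integer_ else i[1]
  }
  rows <- lapply(seq_len(nrow(strata)), function(s) {
    in_tp <- which(vapply(tp_vol, bin_of, integer(1)) == s)
    data.frame(
      volume_bin = strata$label[s],
      n_tp = length(in_tp),
      n_fn = sum(vapply(fn_vol, bin_of, integer(1)) == s, na.rm = TRUE),
      n_fp = sum(vapply(fp_vol, bin_of, integer(1)) == s, na.rm = TRUE),
      mean_dsc = if (length(in_tp) > 0)
        round(mean(tp_dsc[in_tp]), digits) else NA_real_
    )
  })
  all_row <- data.frame(
    volume_bin = "All",
    n_tp = length(tp_vol),
    n_fn = length(fn_vol),
    n_fp = length(fp_vol),
    mean_dsc = if (length(tp_dsc) > 0) round(mean(tp_dsc), digits) else NA_real_
  )
  rbind(do.call(rbind, rows), all_row)
}
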