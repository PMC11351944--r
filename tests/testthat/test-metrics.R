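test_that("detection rates reproduce the published worked examples", {
  # 56 TP, 4 FN -> TPR 0.93; 56 TP, 1 FP -> FPR 0.02 (2 d.p.)
  counts <- detection_counts(n_tp = 56, n_fp = 1, n_fn = 4)
  expect_equal(round(true_positive_rate(counts), 2), 0.93)
  expect_equal(round(false_positive_rate(counts), 2), 0.02)
  expect_equal(true_positive_rate(detection_counts(0, 0, 5)), 0)
  expect_equal(true_positive_rate(detection_counts(7, 0, 0)), 1)
  expect_equal(false_positive_rate(detection_counts(5, 0, 0)), 0)
  expect_equal(false_positive_rate(detection_counts(40, 6, 0)), 6 / 46)
  expect_true(is.na(true_positive_rate(detection_counts(0, 3, 0))))
  expect_true(is.na(false_positive_rate(detection_counts(0, 0, 3))))
})

test_that("voxel dice follows the hard binary definition", {
  gs <- c(6L, 6L, 6L)
  a <- array(0, gs); a[1:4] <- 1
  b <- array(0, gs); b[3:4] <- 1
  # |pred| = 4, |gt| = 2, overlap 2 -> 2*2/(2*2+0+2) = 2/3
  expect_equal(dice_coefficient(a, b), 2 / 3)
  expect_equal(dice_coefficient(a, a), 1)
  d <- array(0, gs); d[10:12] <- 1
  expect_equal(dice_coefficient(a, d), 0)
  expect_true(is.na(dice_coefficient(array(0, gs), array(0, gs))))
})

test_that("lesion matching handles exact, empty and split predictions", {
  gs <- c(20L, 20L, 20L)
  m <- array(0, gs)
  for (i in 0:4) m[3 * i + 1, 1, 1] <- 1  # 5 isolated voxels
  ls <- label_components(m)
  res <- match_lesions(ls, ls)
  expect_equal(res$counts$n_tp, 5)
  expect_equal(res$counts$n_fp, 0)
  expect_equal(res$counts$n_fn, 0)
  expect_true(all(vapply(res$tp_pairs, `[[`, numeric(1), "dsc") == 1))
  empty <- label_components(array(0, gs))
  res2 <- match_lesions(empty, ls)
  expect_equal(unlist(res2$counts), c(n_tp = 0, n_fp = 0, n_fn = 5))
  # one predicted blob spanning two ground-truth lesions: 2 TP, 0 FP
  gt <- array(0, gs); gt[2, 2, 2] <- 1; gt[6, 2, 2] <- 1
  pred <- array(0, gs); pred[2:6, 2, 2] <- 1
  res3 <- match_lesions(label_components(pred), label_components(gt))
  expect_equal(res3$counts$n_tp, 2)
  expect_equal(res3$counts$n_fp, 0)
  # under an IoU threshold the sprawling blob fails to match
  res4 <- match_lesions(label_components(pred), label_components(gt),
                        criterion = "iou", iou_threshold = 0.5)
  expect_equal(res4$counts$n_tp, 0)
  expect_equal(res4$counts$n_fp, 1)
})

test_that("matching counts agree with an exhaustive pairwise-overlap oracle", {
  set.seed(41)
  gs <- c(12L, 12L, 12L)
  for (i in 1:25) {
    pred_m <- random_mask(gs, runif(1, 0.03, 0.15))
    gt_m <- random_mask(gs, runif(1, 0.03, 0.15))
    pls <- label_components(pred_m); gls <- label_components(gt_m)
    res <- match_lesions(pls, gls)
    # oracle: brute-force voxel-set intersections
    pv <- lapply(pls$components, function(co)
      apply(co$voxels, 1, paste, collapse = ","))
    gv <- lapply(gls$components, function(co)
      apply(co$voxels, 1, paste, collapse = ","))
    tp <- sum(vapply(gv, function(g)
      any(vapply(pv, function(p) length(intersect(g, p)) > 0, logical(1))),
      logical(1)))
    fn <- length(gv) - tp
    fp <- sum(vapply(pv, function(p)
      !any(vapply(gv, function(g) length(intersect(g, p)) > 0, logical(1))),
      logical(1)))
    expect_equal(res$counts$n_tp, tp)
    expect_equal(res$counts$n_fn, fn)
    expect_equal(res$counts$n_fp, fp)
  }
})

test_that("whole-image dice is undefined without a TP lesion", {
  gs <- c(10L, 10L, 10L)
  gt <- array(0, gs); gt[2:3, 2, 2] <- 1
  expect_equal(whole_image_dsc(gt, gt), 1)
  miss <- array(0, gs); miss[8, 8, 8] <- 1
  expect_true(is.na(whole_image_dsc(miss, gt)))
  # cohort mean over included images only
  dscs <- c(whole_image_dsc(gt, gt), whole_image_dsc(miss, gt))
  expect_equal(mean(dscs, na.rm = TRUE), 1)
})

test_that("patch-level dice keeps sub-3-voxel fragments and applies the WML rule", {
  gs <- c(8L, 8L, 8L)
  gt <- array(0, gs); gt[4:5, 4, 4] <- 1          # 2-voxel fragment
  wml <- array(0, gs); wml[3:6, 3:6, 3:6] <- 1
  pred <- gt                                       # perfect 2-voxel prediction
  expect_equal(patch_dsc(list(pred), list(gt), list(wml)), 1)
  # prediction outside WML is deleted within the patch
  pred2 <- gt; pred2[1, 1, 1] <- 1
  expect_equal(patch_dsc(list(pred2), list(gt), list(wml)), 1)
  # all patches perfect
  expect_equal(patch_dsc(list(gt, gt), list(gt, gt), list(wml, wml)), 1)
  # no qualifying patch
  expect_true(is.na(patch_dsc(list(array(0, gs)), list(gt), list(wml))))
  # mean equals a per-patch loop
  half <- array(0, gs); half[4, 4, 4] <- 1
  got <- patch_dsc(list(pred, half), list(gt, gt), list(wml, wml))
  expect_equal(got, mean(c(1, dice_coefficient(half, gt))))
})

test_that("volume stratification bins by ground-truth volume and conserves counts", {
  gs <- c(40L, 40L, 40L)
  gt <- array(0, gs)
  gt[1:7, 1, 1] <- 1               # 7 mm^3 lesion -> bin 3-10
  gt[1:15, 5, 1] <- 1              # 15 mm^3 -> 10-20
  gt[1:25, 10, 1] <- 1             # 25 mm^3 -> 20-30
  pred <- gt
  pred[30:35, 30, 30] <- 1         # 6-voxel FP -> FP bin 3-10
  res <- match_lesions(label_components(pred), label_components(gt))
  tab <- stratify_by_volume(res)
  all_row <- tab[tab$volume_bin == "All", ]
  expect_equal(all_row$n_tp, 3)
  expect_equal(all_row$n_fp, 1)
  expect_equal(all_row$n_fn, 0)
  expect_equal(tab$n_tp[tab$volume_bin == "3-10"], 1)
  expect_equal(tab$n_fp[tab$volume_bin == "3-10"], 1)
  bins <- tab[tab$volume_bin != "All", ]
  expect_equal(sum(bins$n_tp), all_row$n_tp)
  expect_equal(sum(bins$n_fn), all_row$n_fn)
  expect_equal(sum(bins$n_fp), all_row$n_fp)
  # counts fed through detection_counts reproduce the published all-row rates
  counts <- detection_counts(all_row$n_tp, all_row$n_fp, all_row$n_fn)
  expect_equal(true_positive_rate(counts), 1)
})
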