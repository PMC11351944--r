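test_that("dice loss matches hand-computed overlaps and limiting cases", {
  # perfect overlap
  gt <- array(c(1, 0, 1, 0, 0, 0, 0, 0), c(2, 2, 2))
  expect_lt(dice_loss(gt, gt), 1e-5)
  # 4 predicted voxels, 2 of them correct: 1 - 2*2/(4+2) = 1/3
  pred <- array(0, c(2, 2, 2)); pred[1:4] <- 1
  gt2 <- array(0, c(2, 2, 2)); gt2[c(1, 3)] <- 1
  expect_equal(dice_loss(pred, gt2, epsilon = 1e-12), 1 / 3, tolerance = 1e-6)
  # empty ground truth with false-positive mass approaches 1
  empty <- array(0, c(2, 2, 2))
  expect_equal(dice_loss(pred, empty, epsilon = 1e-12), 1, tolerance = 1e-6)
  expect_error(dice_loss(pred, array(0, c(3, 3, 3))), "grid")
})

test_that("focal loss reduces to cross-entropy at gamma 0 and has the closed form at p = 0.5", {
  set.seed(2)
  pred <- array(runif(27, 0.05, 0.95), c(3, 3, 3))
  gt <- array(rbinom(27, 1, 0.4), c(3, 3, 3))
  bce <- -mean(gt * log(pred) + (1 - gt) * log(1 - pred))
  expect_equal(focal_loss(pred, gt, gamma = 0), bce, tolerance = 1e-9)
  half <- array(0.5, c(3, 3, 3))
  expect_equal(focal_loss(half, gt, gamma = 2), 0.25 * log(2), tolerance = 1e-9)
  # perfect prediction drives the loss to ~0 (clamped at 1e-7)
  expect_lt(focal_loss(gt, gt, gamma = 2), 1e-6)
})

test_that("loss gradients agree with finite differences", {
  set.seed(3)
  pred <- array(runif(27, 0.1, 0.9), c(3, 3, 3))
  gt <- array(rbinom(27, 1, 0.3), c(3, 3, 3))
  h <- 1e-6
  for (i in c(1, 9, 27)) {
    p1 <- pred; p1[i] <- p1[i] + h
    p2 <- pred; p2[i] <- p2[i] - h
    expect_equal(celseg:::dice_loss_grad(pred, gt)[i],
                 (dice_loss(p1, gt) - dice_loss(p2, gt)) / (2 * h),
                 tolerance = 1e-4)
    expect_equal(celseg:::focal_loss_grad(pred, gt, 2)[i],
                 (focal_loss(p1, gt, 2) - focal_loss(p2, gt, 2)) / (2 * h),
                 tolerance = 1e-4)
  }
})

test_that("starting loss combines per-patch dice and focal means", {
  set.seed(4)
  preds <- lapply(1:5, function(i) array(runif(8, 0.05, 0.95), c(2, 2, 2)))
  gts <- lapply(1:5, function(i) array(rbinom(8, 1, 0.4), c(2, 2, 2)))
  cfg <- loss_config()
  # batch of one
  expect_equal(starting_loss(preds[1], gts[1], cfg),
               0.5 * dice_loss(preds[[1]], gts[[1]], cfg$epsilon) +
                 focal_loss(preds[[1]], gts[[1]], cfg$gamma),
               tolerance = 1e-12)
  # mixed batch vs per-patch loop oracle
  d <- f <- 0
  for (i in 1:5) {
    d <- d + dice_loss(preds[[i]], gts[[i]], cfg$epsilon)
    f <- f + focal_loss(preds[[i]], gts[[i]], cfg$gamma)
  }
  expect_equal(starting_loss(preds, gts, cfg), 0.5 * d / 5 + f / 5,
               tolerance = 1e-9)
  # near-perfect predictions give a near-zero loss
  perf <- lapply(gts, function(g) pmin(pmax(g, 1e-6), 1 - 1e-6))
  expect_lt(starting_loss(perf, gts, cfg), 1e-4)
})

test_that("weighted loss divides the negative dice term by the imbalance rate", {
  # construct one positive patch with dice loss 0.4 and one negative with 1.0
  gt_pos <- array(0, c(2, 2, 2)); gt_pos[c(1, 2)] <- 1
  pred_pos <- array(0, c(2, 2, 2))
  pred_pos[c(1, 2)] <- 1     # S = 2, and spread 8/3 of extra mass so that
  pred_pos[3:6] <- 2 / 3     # P + G = 20/3 and 1 - 4/(20/3) = 0.4
  gt_neg <- array(0, c(2, 2, 2))
  pred_neg <- array(0, c(2, 2, 2)); pred_neg[1] <- 0.7
  cfg <- loss_config(rate_imbalance = 29, epsilon = 1e-12)
  expect_equal(dice_loss(pred_pos, gt_pos, 1e-12), 0.4, tolerance = 1e-9)
  expect_equal(dice_loss(pred_neg, gt_neg, 1e-12), 1, tolerance = 1e-9)
  focal_term <- mean(c(focal_loss(pred_pos, gt_pos, 2),
                       focal_loss(pred_neg, gt_neg, 2)))
  w <- weighted_loss(list(pred_pos, pred_neg), list(gt_pos, gt_neg),
                     config = cfg)
  expect_equal(w - focal_term, (0.4 + 1 / 29) / 2, tolerance = 1e-6)
  # the opposite weighting direction multiplies instead
  cfg_mult <- loss_config(rate_imbalance = 29, epsilon = 1e-12,
                          multiply_negative = TRUE)
  w2 <- weighted_loss(list(pred_pos, pred_neg), list(gt_pos, gt_neg),
                      config = cfg_mult)
  expect_equal(w2 - focal_term, (0.4 + 29) / 2, tolerance = 1e-6)
})

test_that("weighted loss with unit rate equals the starting loss at dice weight 1", {
  set.seed(5)
  preds <- lapply(1:4, function(i) array(runif(27, 0.05, 0.95), c(3, 3, 3)))
  gts <- c(lapply(1:2, function(i) array(rbinom(27, 1, 0.4), c(3, 3, 3))),
           lapply(1:2, function(i) array(0, c(3, 3, 3))))
  cfg1 <- loss_config(rate_imbalance = 1)
  cfg_sw <- loss_config(dice_weight_starting = 1)
  expect_equal(weighted_loss(preds, gts, config = cfg1),
               starting_loss(preds, gts, cfg_sw), tolerance = 1e-12)
})

test_that("negative-patch gradients shrink by the imbalance rate", {
  set.seed(6)
  pred_neg <- array(runif(8, 0.2, 0.8), c(2, 2, 2))
  gt_neg <- array(0, c(2, 2, 2))
  pred_pos <- array(runif(8, 0.2, 0.8), c(2, 2, 2))
  gt_pos <- array(1, c(2, 2, 2)) * (array(runif(8), c(2, 2, 2)) < 0.5)
  cfg <- loss_config(rate_imbalance = 29, gamma = 0)
  # isolate the dice part by comparing against gamma-0 focal subtracted grads
  gw <- celseg:::weighted_loss_grad(list(pred_pos, pred_neg),
                                    list(gt_pos, gt_neg), config = cfg)
  fg_pos <- celseg:::focal_loss_grad(pred_pos, gt_pos, 0) / 2
  fg_neg <- celseg:::focal_loss_grad(pred_neg, gt_neg, 0) / 2
  dice_part_neg <- gw[[2]] - fg_neg
  dice_ref_neg <- celseg:::dice_loss_grad(pred_neg, gt_neg, cfg$epsilon) / 2
  expect_equal(dice_part_neg, dice_ref_neg / 29, tolerance = 1e-6)
  dice_part_pos <- gw[[1]] - fg_pos
  dice_ref_pos <- celseg:::dice_loss_grad(pred_pos, gt_pos, cfg$epsilon) / 2
  expect_equal(dice_part_pos, dice_ref_pos, tolerance = 1e-6)
})

test_that("imbalance rate is the negative:positive patch ratio", {
  expect_equal(compute_rate_imbalance(c(rep(FALSE, 29), TRUE)), 29)
  expect_equal(compute_rate_imbalance(c(FALSE, TRUE, FALSE, TRUE)), 1)
  expect_equal(compute_rate_imbalance(c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE)), 0.5)
  expect_error(compute_rate_imbalance(rep(FALSE, 5)), "manually")
})
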