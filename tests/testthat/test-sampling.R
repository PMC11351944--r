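test_that("z-score normalization standardizes over the mask only", {
  v <- array(0, c(4, 4, 4))
  m <- array(0, c(4, 4, 4))
  v[1, 1, 1] <- 1; v[2, 1, 1] <- 3
  m[1, 1, 1] <- 1; m[2, 1, 1] <- 1
  out <- zscore_normalize(v, m)
  expect_equal(out[1, 1, 1], -1 / sqrt(2), tolerance = 1e-12)
  expect_equal(out[2, 1, 1], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(sum(out[m == 0]), 0)

  set.seed(1)
  v <- array(rnorm(8^3, 5, 2), c(8, 8, 8))
  m <- random_mask(c(8, 8, 8), 0.5)
  out <- zscore_normalize(v, m)
  expect_equal(mean(out[m == 1]), 0, tolerance = 1e-9)
  expect_equal(sd(out[m == 1]), 1, tolerance = 1e-6)
  # idempotence
  expect_equal(zscore_normalize(out, m), out, tolerance = 1e-9)
  # brute-force oracle
  expect_equal(out, oracle_zscore(v, m), tolerance = 1e-9)
  # degenerate input
  expect_error(zscore_normalize(array(1, c(8, 8, 8)), m), "variance")
})

test_that("patch centres respect the one-in-three CEL rule and mask support", {
  b <- test_bundle()
  cfg <- sampling_config()
  cs <- sample_patch_centers(b, cfg)
  expect_equal(nrow(cs$centers), 32)
  expect_equal(sum(cs$center_kind == "cel_centered"), 11)
  expect_equal(sum(cs$center_kind == "wml_centered"), 21)
  for (i in seq_len(nrow(cs$centers))) {
    mask <- if (cs$center_kind[i] == "cel_centered") b$cel_mask else b$wml_mask
    expect_equal(mask[cs$centers[i, 1], cs$centers[i, 2], cs$centers[i, 3]], 1)
  }
  # CEL-free scan: all centres on WML
  neg <- b; neg$cel_mask <- array(0, dim(b$cel_mask))
  csn <- sample_patch_centers(neg, cfg)
  expect_true(all(csn$center_kind == "wml_centered"))
  # single-voxel support
  one <- fake_bundle(c(96L, 96L, 96L), wml_voxels = cbind(40, 41, 42))
  cso <- sample_patch_centers(one, cfg)
  expect_true(all(cso$centers[, 1] == 40 & cso$centers[, 2] == 41 &
                  cso$centers[, 3] == 42))
  # empty support errors
  none <- fake_bundle(c(96L, 96L, 96L))
  expect_error(sample_patch_centers(none, cfg), "no sampling support")
})

test_that("initial crops are centred, clamped at boundaries and invertible", {
  b <- fake_bundle(c(96L, 96L, 96L))
  b$t1_post <- array(as.numeric(seq_len(96^3)), c(96, 96, 96))
  cfg <- sampling_config()
  p <- extract_patch(b, c(48, 48, 48), cfg)
  expect_equal(p$origin, c(16, 16, 16))
  expect_equal(dim(p$gt), c(64, 64, 64))
  pc <- extract_patch(b, c(1, 1, 1), cfg)
  expect_equal(pc$origin, c(0, 0, 0))
  ph <- extract_patch(b, c(96, 96, 96), cfg)
  expect_equal(ph$origin, c(32, 32, 32))
  expect_error(extract_patch(b, c(0, 5, 5), cfg), "outside")
  # round trip: writing the block back at its origin reproduces the source
  o <- p$origin
  expect_identical(p$channels[, , , 2],
                   b$t1_post[(o[1] + 1):(o[1] + 64), (o[2] + 1):(o[2] + 64),
                             (o[3] + 1):(o[3] + 64)])
})

test_that("random sub-crop offsets are uniform and labels track content", {
  b <- fake_bundle(c(96L, 96L, 96L), wml_voxels = cbind(48, 48, 48),
                   cel_voxels = cbind(48, 48, 48))
  cfg <- sampling_config(initial_patch = 20L, final_patch = 16L)
  p <- extract_patch(b, c(48, 48, 48), cfg)
  # identity crop when sizes agree
  cfg_id <- sampling_config(initial_patch = 20L, final_patch = 20L)
  expect_equal(random_subcrop(p, cfg_id)$origin, p$origin)
  # distributional check: offsets uniform on {0..4} per axis
  set.seed(11)
  draws <- t(replicate(3000, random_subcrop(p, cfg)$origin - p$origin))
  for (a in 1:3) {
    tab <- tabulate(draws[, a] + 1, nbins = 5)
    expect_gt(chisq.test(tab)$p.value, 0.001)
  }
  # a lesion voxel excluded by a forced offset flips the label
  bc <- fake_bundle(c(96L, 96L, 96L), wml_voxels = cbind(40, 40, 40),
                    cel_voxels = cbind(31, 31, 31))  # origin 30: local (1,1,1)
  pc <- extract_patch(bc, c(40, 40, 40), cfg)
  expect_true(pc$is_positive)
  sub <- random_subcrop(pc, cfg, offset = c(4, 4, 4))
  expect_false(sub$is_positive)
  sub2 <- random_subcrop(pc, cfg, offset = c(0, 0, 0))
  expect_true(sub2$is_positive)
})

test_that("deterministic flips and rotations are involutions applied to all blocks", {
  b <- test_bundle()
  cfg <- sampling_config(initial_patch = 16L, final_patch = 16L)
  cs <- sample_patch_centers(b, cfg)
  p <- extract_patch(b, cs$centers[1, ], cfg, edge = 16L)
  for (axis in 1:3) {
    expect_identical(flip_patch(flip_patch(p, axis), axis), p)
  }
  expect_identical(rot90_patch(p, c(1, 2), 4), p)
  expect_identical(rot90_patch(rot90_patch(p, c(2, 3), 1), c(2, 3), 3), p)
  # alignment: channels move voxel-identically with gt and wml
  ind <- fake_bundle(c(96L, 96L, 96L), wml_voxels = cbind(40:44, 40, 40),
                     cel_voxels = cbind(40, 40, 40))
  ind$t1_pre <- ind$wml_mask  # channel 1 mirrors the wml mask
  q <- extract_patch(ind, c(42, 40, 40), cfg, edge = 16L)
  fq <- rot90_patch(flip_patch(q, 2), c(1, 3), 1)
  expect_identical(fq$channels[, , , 1], fq$wml)
})

test_that("augmentation keeps masks binary and disabled augmentation is identity", {
  b <- test_bundle()
  cfg_off <- sampling_config(initial_patch = 16L, final_patch = 16L,
                             flip = FALSE, rot90 = FALSE, affine = FALSE,
                             intensity_shift = 0)
  cs <- sample_patch_centers(b, cfg_off)
  p <- extract_patch(b, cs$centers[1, ], cfg_off, edge = 16L)
  expect_identical(augment_patch(p, cfg_off), p)
  cfg_on <- sampling_config(initial_patch = 16L, final_patch = 16L)
  set.seed(21)
  for (i in 1:100) {
    a <- augment_patch(p, cfg_on)
    expect_true(all(unique(as.numeric(a$gt)) %in% c(0, 1)))
    expect_true(all(unique(as.numeric(a$wml)) %in% c(0, 1)))
  }
})
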