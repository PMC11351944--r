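test_that("CEL-free probability zero yields an empty ground truth", {
  cfg <- test_phantom_config(p_scan_has_cels = 0)
  b <- generate_scan(cfg, seed = 1)
  expect_equal(sum(b$cel_mask), 0)
})

test_that("bundle invariants hold: shapes, binarity, CELs inside WML", {
  b <- test_bundle()
  expect_equal(dim(b$t1_pre), dim(b$flair))
  expect_equal(dim(b$wml_mask), dim(b$cel_mask))
  expect_true(all(b$wml_mask %in% c(0, 1)))
  expect_true(all(b$cel_mask %in% c(0, 1)))
  expect_true(sum(b$cel_mask) > 0)
  expect_true(all(b$wml_mask[b$cel_mask == 1] == 1))
})

test_that("CELs are hyperintense on post-contrast T1 and WML on FLAIR", {
  b <- test_bundle()
  tissue <- b$brain_mask == 1 & b$wml_mask == 0 & b$confounder_mask == 0
  expect_gt(mean(b$t1_post[b$cel_mask == 1]), mean(b$t1_post[tissue]) + 20)
  expect_gt(mean(b$flair[b$wml_mask == 1]), mean(b$flair[tissue]) + 20)
})

test_that("a degenerate volume distribution produces minimum 3-voxel lesions", {
  cfg <- test_phantom_config(
    cel_volume_lognormal_params = c(log(3), 1e-9),
    cel_count_mean = 1)
  b <- generate_scan(cfg, seed = 7, force_positive = TRUE)
  comps <- label_components(b$cel_mask)$components
  expect_gte(length(comps), 1)
  expect_true(all(vapply(comps, `[[`, numeric(1), "n_voxels") == 3))
})

test_that("identical seeds produce voxel-identical bundles", {
  cfg <- test_phantom_config(n_confounders = 2L)
  b1 <- generate_scan(cfg, seed = 33)
  b2 <- generate_scan(cfg, seed = 33)
  expect_identical(b1$t1_post, b2$t1_post)
  expect_identical(b1$cel_mask, b2$cel_mask)
  expect_identical(b1$wml_mask, b2$wml_mask)
})

test_that("confounder tubes enhance on post-contrast T1 but avoid the WML mask", {
  cfg <- test_phantom_config(n_confounders = 3L)
  b <- generate_scan(cfg, seed = 5)
  expect_gt(sum(b$confounder_mask), 0)
  expect_equal(sum(b$confounder_mask * b$wml_mask), 0)
  tissue <- b$brain_mask == 1 & b$wml_mask == 0 & b$confounder_mask == 0
  expect_gt(mean(b$t1_post[b$confounder_mask == 1]), mean(b$t1_post[tissue]) + 20)
  # FLAIR-isointense, so only WML overlap can separate them from CELs
  expect_lt(abs(mean(b$flair[b$confounder_mask == 1]) - mean(b$flair[tissue])), 10)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(phantom_config(grid_shape = 32), "64")
  expect_error(phantom_config(min_cel_volume_mm3 = 2), "at least 3")
  expect_error(phantom_config(p_scan_has_cels = 1.5), "0, 1")
})

test_that("cohort structure: ownership, positivity, errors", {
  cfg <- test_phantom_config()
  expect_error(generate_cohort(cfg, n_scans = 0), "n_scans")
  expect_error(generate_cohort(cfg, n_scans = 2, n_patients = 3), "n_patients")
  bundles <- generate_cohort(cfg, n_scans = 6, n_patients = 6, seed = 2)
  pats <- vapply(bundles, `[[`, character(1), "patient_id")
  expect_equal(length(unique(pats)), 6)
  cfg_pos <- test_phantom_config(p_scan_has_cels = 1)
  pos <- generate_cohort(cfg_pos, n_scans = 4, n_patients = 3, seed = 3)
  expect_true(all(vapply(pos, function(b) sum(b$cel_mask) > 0, logical(1))))
  expect_lt(length(unique(vapply(pos, `[[`, character(1), "patient_id"))), 4)
})

test_that("generated lesion counts and volumes match the configured distribution", {
  # Monte-Carlo check of the generator against its own parameters: positive
  # scans carry 1 + Poisson(2) lesions (mean 3) with lognormal volumes of
  # mean ~136 mm^3.
  cfg <- test_phantom_config(p_scan_has_cels = 1, noise_sigma = 0)
  set.seed(99)
  n_scans <- 120
  counts <- integer(n_scans)
  vols <- c()
  for (i in seq_len(n_scans)) {
    b <- generate_scan(cfg)
    comps <- label_components(b$cel_mask)$components
    counts[i] <- length(comps)
    vols <- c(vols, vapply(comps, `[[`, numeric(1), "volume_mm3"))
  }
  mu <- cfg$cel_volume_lognormal_params[1]
  sg <- cfg$cel_volume_lognormal_params[2]
  target_mean_vol <- exp(mu + sg^2 / 2)
  se_count <- sd(counts) / sqrt(n_scans)
  expect_lt(abs(mean(counts) - 3), 2 * se_count + 1e-9)
  se_vol <- sd(vols) / sqrt(length(vols))
  expect_lt(abs(mean(vols) - target_mean_vol), 3 * se_vol)
})

test_that("cohort summary reproduces composition arithmetic", {
  # aggregate worked example: 654 lesions over 208 positive scans out of 372
  set.seed(4)
  n_pos <- 208; n_neg <- 164; total_cels <- 654
  n_cels <- rep(1L, n_pos)
  extra <- total_cels - n_pos
  add <- table(sample.int(n_pos, extra, replace = TRUE))
  n_cels[as.integer(names(add))] <- n_cels[as.integer(names(add))] + as.integer(add)
  man <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n_pos + n_neg)),
    scan_id = sprintf("S%03d", seq_len(n_pos + n_neg)),
    n_cels = c(n_cels, rep(0L, n_neg)))
  s <- cohort_summary(man)
  expect_equal(s$n_scans, 372)
  expect_equal(s$n_cels_total, 654)
  expect_equal(round(s$mean_cels_per_positive_scan), 3)
  expect_equal(round(s$mean_cels_per_scan, 1), 1.8, tolerance = 0.1)

  # one scan with a single 10-voxel lesion at 1 mm^3 per voxel
  vox <- cbind(10:14, 10, 10)
  b <- fake_bundle(c(64L, 64L, 64L), wml_voxels = rbind(vox, cbind(10:14, 11, 10)),
                   cel_voxels = rbind(vox, cbind(10:14, 11, 10)))
  s1 <- cohort_summary(list(b))
  expect_equal(s1$mean_cel_volume_mm3, 10)

  # all-negative cohort
  neg <- fake_bundle(c(64L, 64L, 64L), wml_voxels = cbind(20, 20, 20))
  s0 <- cohort_summary(list(neg))
  expect_equal(s0$n_cels_total, 0)
  expect_true(is.na(s0$mean_cel_volume_mm3) || s0$n_cels_total == 0)
  expect_error(cohort_summary(list()), "non-empty")
})

test_that("NIfTI round trip preserves every volume", {
  b <- test_bundle()
  dir <- withr::local_tempdir()
  write_scan_bundle(b, dir)
  rb <- read_scan_bundle(dir, b$scan_id)
  expect_equal(as.numeric(rb$t1_post), as.numeric(b$t1_post), tolerance = 1e-6)
  expect_identical(as.numeric(rb$cel_mask), as.numeric(b$cel_mask))
  expect_identical(as.numeric(rb$wml_mask), as.numeric(b$wml_mask))
})
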