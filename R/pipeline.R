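#' Evaluate a trained model on a set of scans
#'
#' Runs WML-guided inference, postprocessing and lesion-level evaluation on
#' each scan, then pools the lesion tallies across scans: detection counts
#' and rates, mean whole-image dice over scans with at least one TP lesion,
#' a pooled volume-stratified table, and the number of surviving false
#' positives that coincide with vessel-like confounders (when the bundles
#' carry a \code{confounder_mask}).
#'
#' @param model A \code{celseg_model}.
#' @param bundles List of \code{scan_bundle}s (raw intensities).
#' @param edge Inference window edge.
#' @param threshold Binarization threshold.
#' @param min_voxels,min_wml_fraction Postprocessing parameters.
#' @param mode Reconstruction mode passed to [infer_scan()].
#' @return List with \code{counts} ([detection_counts()]), \code{tpr},
#'   \code{fpr}, \code{mean_whole_image_dsc}, \code{mean_lesion_dsc},
#'   \code{stratified} (data frame), \code{per_scan} (data frame),
#'   \code{confounder_fps}.
#' @export
evaluate_scans <- function(model, bundles, edge = 48L, threshold = 0.5,
                           min_voxels = 3, min_wml_fraction = 0.10,
                           mode = "union") {
  tp_vol <- tp_dsc <- fn_vol <- fp_vol <- numeric(0)
  wi_dsc <- numeric(0)
  conf_fp <- 0L
  per_scan <- NULL
  for (b in bundles) {
    pred <- infer_scan(model, b, edge = edge, threshold = threshold,
                       mode = mode)
    pred <- postprocess_prediction(pred, b$wml_mask, min_voxels,
                                   min_wml_fraction,
                                   voxel_size_mm = b$voxel_size_mm)
    pls <- label_components(pred, voxel_size_mm = b$voxel_size_mm)
    gls <- label_components(b$cel_mask, voxel_size_mm = b$voxel_size_mm)
    m <- match_lesions(pls, gls)
    tp_vol <- c(tp_vol, vapply(m$tp_pairs, `[[`, numeric(1), "gt_volume_mm3"))
    tp_dsc <- c(tp_dsc, vapply(m$tp_pairs, `[[`, numeric(1), "dsc"))
    fn_vol <- c(fn_vol, vapply(m$fn_components, function(i)
      gls$components[[i]]$volume_mm3, numeric(1)))
    fp_vol <- c(fp_vol, vapply(m$fp_components, function(i)
      pls$components[[i]]$volume_mm3, numeric(1)))
    if (!is.null(b$confounder_mask)) {
      for (i in m$fp_components) {
        if (any(b$confounder_mask[pls$components[[i]]$voxels] == 1)) {
          conf_fp <- conf_fp + 1L
        }
      }
    }
    d <- whole_image_dsc(pred, b$cel_mask)
    if (!is.na(d)) wi_dsc <- c(wi_dsc, d)
    per_scan <- rbind(per_scan, data.frame(
      scan_id = b$scan_id, n_tp = m$counts$n_tp, n_fp = m$counts$n_fp,
      n_fn = m$counts$n_fn, whole_image_dsc = d))
  }
  counts <- detection_counts(n_tp = length(tp_vol), n_fp = length(fp_vol),
                             n_fn = length(fn_vol))
  list(counts = counts,
       tpr = true_positive_rate(counts),
       fpr = false_positive_rate(counts),
       mean_whole_image_dsc = if (length(wi_dsc)) mean(wi_dsc) else NA_real_,
       mean_lesion_dsc = if (length(tp_dsc)) mean(tp_dsc) else NA_real_,
       stratified = stratify_vectors(tp_vol, tp_dsc, fn_vol, fp_vol),
       per_scan = per_scan,
       confounder_fps = conf_fp)
}

#' Default end-to-end pipeline configuration
#'
#' A desk-scale demo profile: 20 synthetic scans from 16 patients, a reduced
#' network width (8, 16 filters over two levels), 24-voxel final patches and
#' a raised learning rate so training converges on a CPU in minutes. Every
#' block can be overridden through \code{overrides} (nested lists mirroring
#' the block structure) or a YAML file with blocks \code{phantom},
#' \code{sampling}, \code{network}, \code{loss}, \code{train},
#' \code{cohort}.
#'
#' @param path Optional YAML file path.
#' @param overrides Optional nested list of overrides applied on top.
#' @return Nested configuration list.
#' @export
pipeline_config <- function(path = NULL, overrides = NULL) {
  cfg <- list(
    cohort = list(n_scans = 20L, n_patients = 16L, seed = 20L),
    phantom = list(),
    sampling = list(patches_per_scan = 16L, initial_patch = 24L,
                    final_patch = 16L),
    network = list(in_channels = 3L, encoder_filters = c(8L, 16L),
                   decoder_filters = c(16L, 8L), stride = 2L),
    loss = list(gamma = 2, rate_imbalance = 29),
    train = list(learning_rate = 3e-3, epochs = 30L, batch_size = 8L,
                 n_folds = 5L, loss = "weighted", rate_mode = "auto",
                 val_interval = 5L,
                 early_stop_patience = 20L, seed = 7L),
    postprocess = list(min_voxels = 3, min_wml_fraction = 0.10),
    inference = list(mode = "average")
  )
  merge_block <- function(base, extra) {
    for (nm in names(extra)) {
      if (is.list(extra[[nm]]) && is.list(base[[nm]])) {
        base[[nm]] <- merge_block(base[[nm]], extra[[nm]])
      } else {
        base[[nm]] <- extra[[nm]]
      }
    }
    base
  }
  if (!is.null(path)) cfg <- merge_block(cfg, yaml::read_yaml(path))
  if (!is.null(overrides)) cfg <- merge_block(cfg, overrides)
  cfg
}

#' Run the full pipeline on synthetic data
#'
#' Generates a cohort, splits it into patient-level folds (fold 1 test,
#' fold 2 validation, the rest training in the default single rotation),
#' trains the network, and evaluates the test fold end to end. When
#' \code{compare_losses} is TRUE both the starting and the weighted loss are
#' trained under identical seeds and both result sets are reported.
#'
#' @param config A [pipeline_config()] list (or a YAML path).
#' @param output_dir Optional directory for CSV reports (summary, stratified
#'   table, training history).
#' @param compare_losses Train both loss variants instead of only the
#'   configured one.
#' @param verbose Print progress.
#' @return List with \code{evaluation} (per trained loss), \code{summary}
#'   (one row per loss), \code{stratified}, \code{history}, \code{folds}.
#' @export
run_end_to_end <- function(config = pipeline_config(), output_dir = NULL,
                           compare_losses = FALSE, verbose = FALSE) {
  if (is.character(config)) config <- pipeline_config(path = config)
  ph <- do.call(phantom_config, config$phantom)
  sc <- do.call(sampling_config, config$sampling)
  nc <- do.call(network_config, config$network)
  lc <- do.call(loss_config, config$loss)
  tc <- do.call(train_config, config$train)
  co <- config$cohort
  bundles <- generate_cohort(ph, n_scans = co$n_scans,
                             n_patients = co$n_patients, seed = co$seed)
  folds <- split_folds(bundles, n_folds = tc$n_folds, seed = co$seed)
  fold_of <- folds$assignments$fold
  test_b <- bundles[fold_of == folds$test_fold]
  val_fold <- setdiff(sort(unique(fold_of)), folds$test_fold)[1]
  val_b <- bundles[fold_of == val_fold]
  train_b <- bundles[!(fold_of %in% c(folds$test_fold, val_fold))]
  stopifnot(length(intersect(
    vapply(train_b, `[[`, character(1), "patient_id"),
    c(vapply(val_b, `[[`, character(1), "patient_id"),
      vapply(test_b, `[[`, character(1), "patient_id")))) == 0)
  losses <- if (compare_losses) c("starting", "weighted") else tc$loss
  pp <- config$postprocess
  evaluation <- list()
  history <- list()
  models <- list()
  summary_rows <- NULL
  for (lo in losses) {
    tc_lo <- tc; tc_lo$loss <- lo
    fit <- train_fold(train_b, val_b, nc, sc, lc, tc_lo,
                      min_voxels = pp$min_voxels,
                      min_wml_fraction = pp$min_wml_fraction,
                      inference_mode = config$inference$mode,
                      verbose = verbose)
    ev <- evaluate_scans(fit$model, test_b, edge = sc$final_patch,
                         threshold = tc$threshold,
                         min_voxels = pp$min_voxels,
                         min_wml_fraction = pp$min_wml_fraction,
                         mode = config$inference$mode)
    evaluation[[lo]] <- ev
    history[[lo]] <- fit$history
    models[[lo]] <- fit$model
    summary_rows <- rbind(summary_rows, data.frame(
      loss = lo, n_tp = ev$counts$n_tp, n_fn = ev$counts$n_fn,
      n_fp = ev$counts$n_fp, tpr = ev$tpr, fpr = ev$fpr,
      whole_image_dsc = ev$mean_whole_image_dsc,
      lesion_dsc = ev$mean_lesion_dsc,
      best_val_dsc = fit$best_val_dsc,
      confounder_fps = ev$confounder_fps))
  }
  out <- list(evaluation = evaluation, summary = summary_rows,
              stratified = evaluation[[length(evaluation)]]$stratified,
              history = history, models = models, folds = folds)
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    write.csv(summary_rows, file.path(output_dir, "summary.csv"),
              row.names = FALSE)
    write.csv(out$stratified, file.path(output_dir, "stratified.csv"),
              row.names = FALSE)
    for (lo in names(history)) {
      write.csv(history[[lo]],
                file.path(output_dir, sprintf("history_%s.csv", lo)),
                row.names = FALSE)
    }
    for (lo in names(evaluation)) {
      saveRDS(list(model = models[[lo]], edge = sc$final_patch,
                   config = config),
              file.path(output_dir, sprintf("model_%s.rds", lo)))
    }
  }
  out
}
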