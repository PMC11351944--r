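#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 5e-5, the value used at
#'   full clinical scale; desk-scale demo profiles typically raise it).
#' @param epochs Maximum training epochs.
#' @param batch_size Patches per optimizer step.
#' @param n_folds Number of patient-level cross-validation folds (default 11).
#' @param loss \code{"weighted"} (default) or \code{"starting"}.
#' @param rate_mode \code{"fixed"} uses \code{loss_config$rate_imbalance};
#'   \code{"auto"} recomputes it from the first epoch's patch labels.
#' @param val_interval Validate (and checkpoint) every this many epochs.
#' @param early_stop_patience Stop after this many validations without
#'   improvement of the whole-image validation dice.
#' @param threshold Binarization threshold at inference.
#' @param seed Seed for initialization and sampling.
#' @return An object of class \code{train_config}.
#' @export
train_config <- function(learning_rate = 5e-5, epochs = 100L, batch_size = 8L,
                         n_folds = 11L, loss = c("weighted", "starting"),
                         rate_mode = c("fixed", "auto"), val_interval = 1L,
                         early_stop_patience = 20L, threshold = 0.5,
                         seed = NULL) {
  loss <- match.arg(loss)
  rate_mode <- match.arg(rate_mode)
  stopifnot(learning_rate > 0, n_folds >= 3, epochs >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 n_folds = as.integer(n_folds), loss = loss,
                 rate_mode = rate_mode, val_interval = as.integer(val_interval),
                 early_stop_patience = as.integer(early_stop_patience),
                 threshold = threshold, seed = seed),
            class = "train_config")
}

#' Patient-level cross-validation folds
#'
#' Randomly partitions patients (never scans) into \code{n_folds} subgroups,
#' so all scans of a patient land in the same fold and no patient can leak
#' between training, validation and test. One fold is fixed as the test set;
#' the remaining folds rotate between validation and training.
#'
#' @param manifest Data frame with columns \code{patient_id} and
#'   \code{scan_id} (one row per scan), or a list of \code{scan_bundle}s.
#' @param n_folds Number of folds.
#' @param seed Optional RNG seed.
#' @return List with \code{patient_fold} (named integer vector),
#'   \code{assignments} (manifest plus a \code{fold} column) and
#'   \code{test_fold} (fixed at 1).
#' @export
split_folds <- function(manifest, n_folds = 11L, seed = NULL) {
  if (!is.data.frame(manifest)) {
    manifest <- data.frame(
      patient_id = vapply(manifest, function(b) b$patient_id, character(1)),
      scan_id = vapply(manifest, function(b) b$scan_id, character(1)))
  }
  patients <- unique(manifest$patient_id)
  if (length(patients) < n_folds) {
    stop(sprintf("need at least %d patients for %d folds", n_folds, n_folds),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  shuffled <- sample(patients)
  fold <- rep(seq_len(n_folds), length.out = length(patients))
  patient_fold <- stats::setNames(fold[match(patients, shuffled)], patients)
  manifest$fold <- unname(patient_fold[manifest$patient_id])
  list(patient_fold = patient_fold, assignments = manifest, test_fold = 1L)
}

# --- Adam over the nested parameter tree ------------------------------------

# Numeric leaves of the model tree addressed through the gradient tree (the
# gradient tree carries exactly the trainable leaves: W, b, alpha1, alpha2).
#' @noRd
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) out[[nm]] <- tree_map2(a[[nm]], b[[nm]], f)
    out
  } else {
    f(a, b)
  }
}

#' @noRd
tree_map <- function(a, f) {
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- tree_map(a[[nm]], f)
    a
  } else {
    f(a)
  }
}

#' @noRd
grad_add <- function(g1, g2) tree_map2(g1, g2, `+`)

#' @noRd
grad_scale <- function(g, s) tree_map(g, function(x) x * s)

# Apply one Adam update; model leaves are addressed via the gradient tree so
# non-trainable fields (k, stride, config) are untouched.
#' @noRd
adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  if (is.null(state)) {
    state <- list(m = grad_scale(grads, 0), v = grad_scale(grads, 0), t = 0L)
  }
  state$t <- state$t + 1L
  state$m <- tree_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- tree_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(state$m, state$v,
                   function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  apply_update <- function(params, delta) {
    if (is.list(delta)) {
      for (nm in names(delta)) {
        params[[nm]] <- apply_update(params[[nm]], delta[[nm]])
      }
      params
    } else {
      params - delta
    }
  }
  model$enc <- lapply(seq_along(model$enc), function(i)
    apply_update(model$enc[[i]], upd$enc[[i]]))
  model$dec <- lapply(seq_along(model$dec), function(i)
    apply_update(model$dec[[i]], upd$dec[[i]]))
  model$head <- apply_update(model$head, upd$head)
  list(model = model, state = state)
}

# One optimizer step on a batch of patches; returns model, state, loss value.
#' @noRd
train_batch <- function(model, batch, loss_cfg, loss_kind, opt_state, lr) {
  fwd <- lapply(batch, function(p) unet_forward(model, p$channels,
                                                want_cache = TRUE))
  preds <- lapply(fwd, `[[`, "prob")
  gts <- lapply(batch, `[[`, "gt")
  flags <- vapply(batch, `[[`, logical(1), "is_positive")
  if (loss_kind == "weighted") {
    lv <- weighted_loss(preds, gts, flags, loss_cfg)
    dl <- weighted_loss_grad(preds, gts, flags, loss_cfg)
  } else {
    lv <- starting_loss(preds, gts, loss_cfg)
    dl <- starting_loss_grad(preds, gts, loss_cfg)
  }
  total <- NULL
  for (i in seq_along(batch)) {
    g <- unet_backward(model, fwd[[i]]$cache, dl[[i]])
    total <- if (is.null(total)) g else grad_add(total, g)
  }
  st <- adam_step(model, total, opt_state, lr)
  list(model = st$model, state = st$state, loss = lv)
}

#' Train the network on one cross-validation fold
#'
#' Per epoch, patches are sampled afresh from every training scan
#' (two-stage crop plus augmentation), grouped into batches and used for
#' Adam steps on the selected loss. At each validation interval every
#' validation scan is segmented end-to-end (WML-guided inference,
#' reconstruction, postprocessing) and the mean whole-image dice over
#' validation scans is recorded; the returned model is the checkpoint with
#' the highest validation dice. Patient-level leakage between the two sets
#' is checked up front.
#'
#' @param train_bundles,val_bundles Lists of \code{scan_bundle}s (raw
#'   intensities; normalized internally once).
#' @param net_config A [network_config()].
#' @param samp_config A [sampling_config()]; its \code{final_patch} is also
#'   the inference window edge.
#' @param loss_cfg A [loss_config()].
#' @param train_cfg A [train_config()].
#' @param min_voxels,min_wml_fraction Postprocessing parameters used during
#'   validation.
#' @param inference_mode Reconstruction mode passed to [infer_scan()] at
#'   validation time (\code{"union"} or \code{"average"}).
#' @param verbose Print per-epoch progress.
#' @return List with \code{model} (best checkpoint), \code{final_model},
#'   \code{history} (per-epoch data frame), \code{best_val_dsc},
#'   \code{rate_imbalance}.
#' @export
train_fold <- function(train_bundles, val_bundles, net_config, samp_config,
                       loss_cfg = loss_config(), train_cfg = train_config(),
                       min_voxels = 3, min_wml_fraction = 0.10,
                       inference_mode = "union", verbose = FALSE) {
  stopifnot(length(train_bundles) > 0, length(val_bundles) > 0)
  tr_pat <- unique(vapply(train_bundles, `[[`, character(1), "patient_id"))
  va_pat <- unique(vapply(val_bundles, `[[`, character(1), "patient_id"))
  if (length(intersect(tr_pat, va_pat)) > 0) {
    stop("patient-level leakage: patients shared between training and validation",
         call. = FALSE)
  }
  if (!any(vapply(val_bundles, function(b) sum(b$cel_mask) > 0, logical(1)))) {
    stop("validation set has no CEL-positive scan; the whole-image dice model-selection metric is undefined. Add a positive scan to the validation fold.",
         call. = FALSE)
  }
  if (!is.null(train_cfg$seed)) set.seed(train_cfg$seed)
  train_norm <- lapply(train_bundles, normalize_bundle)
  val_norm <- lapply(val_bundles, normalize_bundle)
  model <- build_model(net_config)
  opt_state <- NULL
  best <- list(model = model, dsc = -Inf, epoch = 0L)
  history <- NULL
  validations_since_best <- 0L
  edge <- samp_config$final_patch
  for (epoch in seq_len(train_cfg$epochs)) {
    epoch_losses <- c()
    labels <- logical(0)
    for (b in sample(seq_along(train_norm))) {
      patches <- sample_training_patches(train_norm[[b]], samp_config)
      labels <- c(labels, vapply(patches, `[[`, logical(1), "is_positive"))
      idx <- sample(seq_along(patches))
      starts <- seq(1, length(idx), by = train_cfg$batch_size)
      for (s in starts) {
        take <- idx[s:min(s + train_cfg$batch_size - 1, length(idx))]
        st <- train_batch(model, patches[take], loss_cfg, train_cfg$loss,
                          opt_state, train_cfg$learning_rate)
        model <- st$model; opt_state <- st$state
        epoch_losses <- c(epoch_losses, st$loss)
      }
    }
    if (epoch == 1 && train_cfg$rate_mode == "auto" && any(labels)) {
      loss_cfg$rate_imbalance <- max(compute_rate_imbalance(labels),
                                     .Machine$double.eps)
    }
    val_dsc <- NA_real_
    if (epoch %% train_cfg$val_interval == 0 || epoch == train_cfg$epochs) {
      dscs <- vapply(val_norm, function(vb) {
        pred <- infer_scan(model, vb, edge = edge,
                           threshold = train_cfg$threshold, normalized = TRUE,
                           mode = inference_mode)
        pred <- postprocess_prediction(pred, vb$wml_mask, min_voxels,
                                       min_wml_fraction)
        whole_image_dsc(pred, vb$cel_mask)
      }, numeric(1))
      val_dsc <- if (all(is.na(dscs))) 0 else mean(dscs, na.rm = TRUE)
      if (val_dsc > best$dsc) {
        best <- list(model = model, dsc = val_dsc, epoch = epoch)
        validations_since_best <- 0L
      } else {
        validations_since_best <- validations_since_best + 1L
      }
    }
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = mean(epoch_losses), val_dsc = val_dsc,
      best_val_dsc = if (is.finite(best$dsc)) best$dsc else NA_real_))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val DSC %s", epoch,
                      mean(epoch_losses),
                      ifelse(is.na(val_dsc), "-", sprintf("%.3f", val_dsc))))
    }
    if (validations_since_best >= train_cfg$early_stop_patience) break
  }
  list(model = best$model, final_model = model, history = history,
       best_val_dsc = best$dsc, best_epoch = best$epoch,
       rate_imbalance = loss_cfg$rate_imbalance)
}

#' Train a model on a fixed patch set
#'
#' Lightweight trainer used for loss-function comparisons and overfitting
#' sanity checks: repeatedly draws batches from a fixed list of patches and
#' applies Adam steps on the selected loss.
#'
#' @param patches List of \code{cel_patch} objects (final edge length).
#' @param net_config A [network_config()].
#' @param loss \code{"weighted"} or \code{"starting"}.
#' @param steps Number of optimizer steps.
#' @param batch_size Patches per step (capped at the patch count).
#' @param learning_rate Adam learning rate.
#' @param loss_cfg A [loss_config()].
#' @param seed Optional seed (initialization and batch order).
#' @return List with \code{model} and \code{losses} (per-step values).
#' @export
train_on_patches <- function(patches, net_config, loss = "weighted",
                             steps = 100L, batch_size = 8L,
                             learning_rate = 1e-3,
                             loss_cfg = loss_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  model <- build_model(net_config)
  opt_state <- NULL
  losses <- numeric(steps)
  bs <- min(batch_size, length(patches))
  for (s in seq_len(steps)) {
    take <- sample.int(length(patches), bs)
    st <- train_batch(model, patches[take], loss_cfg, loss, opt_state,
                      learning_rate)
    model <- st$model; opt_state <- st$state
    losses[s] <- st$loss
  }
  list(model = model, losses = losses)
}

#' Mean dice over the positive patches of a patch set
#'
#' Predicts every patch whose ground truth contains a lesion voxel and
#' averages the hard dice at the given threshold — the patch-level quantity
#' used to compare training losses.
#'
#' @param model A \code{celseg_model}.
#' @param patches List of \code{cel_patch} objects.
#' @param threshold Binarization threshold.
#' @return Mean dice over positive patches (NA if none).
#' @export
mean_positive_patch_dsc <- function(model, patches, threshold = 0.5) {
  pos <- Filter(function(p) p$is_positive, patches)
  if (length(pos) == 0) return(NA_real_)
  mean(vapply(pos, function(p) {
    pr <- (unet_forward(model, p$channels)$prob >= threshold) * 1
    d <- dice_coefficient(pr, p$gt)
    if (is.na(d)) 0 else d
  }, numeric(1)))
}

#' Compare the starting and weighted losses on one patch set
#'
#' Trains one model per loss under identical seeds and patch sets, then
#' reports the mean positive-patch dice of each, per seed.
#'
#' @param patches List of \code{cel_patch} objects.
#' @param net_config A [network_config()].
#' @param seeds Integer vector of training seeds.
#' @param steps,batch_size,learning_rate Passed to [train_on_patches()].
#' @param loss_cfg A [loss_config()].
#' @return Data frame with columns \code{seed}, \code{loss},
#'   \code{positive_patch_dsc}.
#' @export
compare_loss_functions <- function(patches, net_config, seeds = 1:3,
                                   steps = 100L, batch_size = 8L,
                                   learning_rate = 1e-3,
                                   loss_cfg = loss_config()) {
  rows <- lapply(seeds, function(sd) {
    do.call(rbind, lapply(c("starting", "weighted"), function(lo) {
      fit <- train_on_patches(patches, net_config, loss = lo, steps = steps,
                              batch_size = batch_size,
                              learning_rate = learning_rate,
                              loss_cfg = loss_cfg, seed = sd)
      data.frame(seed = sd, loss = lo,
                 positive_patch_dsc = mean_positive_patch_dsc(fit$model, patches))
    }))
  })
  do.call(rbind, rows)
}
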