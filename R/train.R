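# Training, inference, patient-level aggregation and threshold tuning.

#' Training configuration
#'
#' The full-scale regime is `train_config_paper()`: batch 32, 110 epochs,
#' learning rate 0.001 for epochs 1-80 then 0.0001 for 81-110, focal gamma 3.
#' The default here is the desk-scale regime used by the test-suite: 10
#' epochs with the switch at epoch 9 (the same 8:2 high/low-rate proportion),
#' light color jitter without blur.
#'
#' @param epochs total training epochs.
#' @param batch_size minibatch size.
#' @param lr learning rate before the switch epoch.
#' @param lr_after learning rate from the switch epoch on.
#' @param lr_switch_epoch first epoch that uses `lr_after`; `NULL` places the
#'   switch at the full schedule's 80/110 proportion of `epochs`.
#' @param focal_gamma focal-loss focusing exponent.
#' @param seed RNG seed covering initialisation, shuffling, crops and
#'   augmentation draws.
#' @param augment an [augmentation_config()] applied to every training crop;
#'   inference never augments.  The desk default keeps the full geometric
#'   group but scales the color jitter down (the jitter magnitudes are free
#'   configuration, and a 10-epoch run cannot average over strong color
#'   perturbations the way a 110-epoch run can); `train_config_paper()` uses
#'   the full-strength jitter.
#' @param crop a [crop_spec()], or `NULL` to derive one per source size via
#'   [default_crop_spec()].
#' @return a `train_config` object.
#' @export
train_config <- function(epochs = 10, batch_size = 32, lr = 0.001,
                         lr_after = 1e-4, lr_switch_epoch = NULL,
                         focal_gamma = 3, seed = 1,
                         augment = augmentation_config(
                           gamma_range = c(0.95, 1.05),
                           saturation_range = c(0.95, 1.05),
                           temperature_range = c(0.98, 1.02),
                           noise_sigma = 0.005,
                           blur_sigma_range = c(0, 0)),
                         crop = NULL) {
  if (!is_count(epochs) || epochs < 1) stopf("epochs must be a positive integer")
  # default switch keeps the 80:30 high/low proportion of the full schedule
  if (is.null(lr_switch_epoch)) lr_switch_epoch <- floor(epochs * 80 / 110) + 1
  if (lr_switch_epoch < 1 || lr_switch_epoch > epochs + 1)
    stopf("lr_switch_epoch must lie in [1, epochs + 1]")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, lr_after = lr_after,
                 lr_switch_epoch = as.integer(lr_switch_epoch),
                 focal_gamma = focal_gamma, seed = as.integer(seed),
                 augment = augment, crop = crop),
            class = "train_config")
}

#' @rdname train_config
#' @export
train_config_paper <- function(seed = 1) {
  train_config(epochs = 110, batch_size = 32, lr = 0.001, lr_after = 1e-4,
               lr_switch_epoch = 81, focal_gamma = 3, seed = seed,
               augment = augmentation_config())
}

# Preprocess one raw core image for the network: crop (random in training,
# center at inference), resize to the input side, augment (training only).
prepare_input <- function(img, side, spec = NULL, aug = NULL) {
  if (is.null(spec)) spec <- default_crop_spec(dim(img)[1:2])
  x <- if (is.null(aug)) center_crop(img, spec) else random_crop_train(img, spec)
  x <- resize_to_input(x, side)
  if (!is.null(aug)) x <- augment(x, aug)
  attributes(x) <- list(dim = dim(x))
  x
}

make_batch <- function(images, idx, side, spec, aug) {
  xb <- array(0, c(side, side, 3, length(idx)))
  for (k in seq_along(idx))
    xb[, , , k] <- prepare_input(images[[idx[k]]], side, spec, aug)
  xb
}

#' Fit the residual CNN to weakly labelled core images
#'
#' Trains the stem + 4-residual-block network with focal loss under the
#' RAdam optimizer on patient-level weak labels (every image inherits its
#' patient's label).  Returns a fitted model with `print`, `summary` and
#' `predict` methods; `predict` runs the deterministic inference path.
#'
#' @param images list of raw core images (height x width x 3 arrays).
#' @param labels integer 0/1 (or logical) image labels, aligned with
#'   `images`.
#' @param config a [cnn_config()]; defaults to the desk-scale architecture.
#' @param train a [train_config()].
#' @param threshold operating threshold stored with the model (0.5 is the
#'   shipped PD-L1 default; 0.28 for PD-1).
#' @param verbose print the per-epoch loss.
#' @return an object of class `hecnn`: the network, its configs, the
#'   operating `threshold`, and a per-epoch `history` (epoch, loss, lr).
#' @export
hecnn <- function(images, labels, config = cnn_config_desk(),
                  train = train_config(), threshold = 0.5, verbose = FALSE) {
  if (length(images) == 0) stopf("empty training set")
  labels <- as.integer(labels)
  if (length(labels) != length(images)) stopf("labels must align with images")
  if (length(unique(labels)) < 2)
    warning("training set has a single class; focal loss is degenerate")
  net <- build_model(config, seed = train$seed)
  opt <- radam_state(net$params)
  n <- length(images)
  history <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))
  with_seed(train$seed + 1L, {
    for (epoch in seq_len(train$epochs)) {
      lr <- if (epoch >= train$lr_switch_epoch) train$lr_after else train$lr
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = train$batch_size)) {
        idx <- ord[start:min(start + train$batch_size - 1, n)]
        xb <- make_batch(images, idx, config$input_side, train$crop, train$augment)
        fw <- forward_cnn(net, xb, training = TRUE)
        loss <- focal_loss(fw$probs, labels[idx], train$focal_gamma)
        dz <- focal_grad_logits(fw$probs, labels[idx], train$focal_gamma)
        gr <- backward_cnn(net, fw, dz)
        up <- radam_step(opt, net$params, gr, lr)
        net$params <- up$params; opt <- up$state; net$bn <- fw$newbn
        ep_loss <- ep_loss + loss; nb <- nb + 1
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, loss = ep_loss / nb, lr = lr))
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  lr %g", epoch, ep_loss / nb, lr))
    }
  })
  structure(list(net = net, config = config, train = train,
                 threshold = threshold, history = history,
                 version = net$version, seed = train$seed),
            class = "hecnn")
}

#' @export
print.hecnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Residual CNN for H&E core images (%d px input)\n", cfg$input_side))
  cat(sprintf("  stem %d -> blocks %s -> embedding %d -> %d classes; %s trainable parameters\n",
              cfg$stem_width, paste(cfg$block_widths, collapse = "/"),
              cfg$embedding_dim, cfg$n_classes,
              format(count_parameters(x), big.mark = ",")))
  cat(sprintf("  trained %d epochs (focal gamma %g), final loss %.4f; threshold %.2f\n",
              nrow(x$history), x$train$focal_gamma,
              tail(x$history$loss, 1), x$threshold))
  invisible(x)
}

#' @export
summary.hecnn <- function(object, ...) {
  print(object)
  cat("\nTraining history (tail):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' Predict scores or embeddings for core images
#'
#' Deterministic inference: center crop, resize, eval-mode forward pass with
#' fixed BatchNorm statistics; no augmentation.  The score is the
#' positive-class softmax probability in `[0, 1]`.
#'
#' @param object a fitted `hecnn` model.
#' @param images list of raw core images, or a single image array.
#' @param type `"score"` (positive-class probability), `"prob"` (n x 2
#'   matrix), or `"embedding"` (n x embedding_dim pre-head features).
#' @param batch_size inference batch size.
#' @param ... unused.
#' @return numeric vector or matrix according to `type`.
#' @export
predict.hecnn <- function(object, images, type = c("score", "prob", "embedding"),
                          batch_size = 64, ...) {
  type <- match.arg(type)
  if (is.array(images)) images <- list(images)
  cfg <- object$config
  n <- length(images)
  out_score <- numeric(n)
  out_prob <- matrix(NA_real_, n, cfg$n_classes)
  out_emb <- matrix(NA_real_, n, cfg$embedding_dim)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    xb <- array(0, c(cfg$input_side, cfg$input_side, 3, length(idx)))
    for (k in seq_along(idx))
      xb[, , , k] <- prepare_input(images[[idx[k]]], cfg$input_side,
                                   object$train$crop, aug = NULL)
    fw <- forward_cnn(object$net, xb, training = FALSE)
    out_score[idx] <- fw$probs[, 2]
    out_prob[idx, ] <- fw$probs
    out_emb[idx, ] <- fw$emb
  }
  switch(type, score = out_score, prob = out_prob, embedding = out_emb)
}

#' Aggregate image scores to patient scores by maximum
#'
#' A patient's prediction score is the maximum of the scores of its H&E
#' images; single-image patients keep that image's score.
#'
#' @param scores numeric image scores in `[0, 1]`.
#' @param patient_ids patient id per image, aligned with `scores`.
#' @return data frame `patient_id`, `score`, `n_images`.
#' @export
aggregate_patient_scores <- function(scores, patient_ids) {
  if (length(scores) != length(patient_ids))
    stopf("scores and patient_ids must align")
  if (length(scores) == 0) stopf("no image scores to aggregate")
  if (any(is.na(scores)))
    stopf("patients with unscored images: %s",
          paste(utils::head(unique(patient_ids[is.na(scores)]), 5), collapse = ", "))
  sp <- split(scores, factor(patient_ids, levels = unique(patient_ids)))
  data.frame(patient_id = names(sp),
             score = vapply(sp, max, 0),
             n_images = lengths(sp), row.names = NULL)
}

#' Patient-level k-fold cross-validation
#'
#' Trains one model per fold on the images of all other folds' patients and
#' scores the held-out fold's images, so every patient is scored exactly once
#' by a model that never saw any of its images.
#'
#' @param images list of raw core images.
#' @param labels integer 0/1 image labels.
#' @param patient_ids patient id per image.
#' @param folds a `split_assignment` from [make_cv_folds()] covering every
#'   patient in `patient_ids`.
#' @param config a [cnn_config()].
#' @param train a [train_config()]; fold f trains with seed
#'   `train$seed + f`.
#' @param verbose print per-fold progress.
#' @return an object of class `hecnn_cv`: `patient_scores` (patient_id,
#'   score, label, partition), `image_scores`, and the per-fold training
#'   histories.
#' @export
hecnn_cv <- function(images, labels, patient_ids, folds,
                     config = cnn_config_desk(), train = train_config(),
                     verbose = FALSE) {
  labels <- as.integer(labels)
  fold_names <- sort(unique(folds$partition))
  miss <- setdiff(unique(patient_ids), folds$patient_id)
  if (length(miss))
    stopf("patients missing from the fold assignment: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  audit_no_leakage(folds, data.frame(patient_id = patient_ids,
                                     image_id = seq_along(patient_ids)))
  part_of <- stats::setNames(folds$partition, folds$patient_id)
  img_part <- part_of[patient_ids]
  res <- vector("list", length(fold_names))
  hists <- list()
  for (f in seq_along(fold_names)) {
    fn <- fold_names[f]
    tr_idx <- which(img_part != fn)
    te_idx <- which(img_part == fn)
    if (!length(te_idx)) stopf("fold %s holds no images", fn)
    tcfg <- train; tcfg$seed <- train$seed + f
    if (verbose) message(sprintf("fold %s: %d train / %d validation images",
                                 fn, length(tr_idx), length(te_idx)))
    fit <- hecnn(images[tr_idx], labels[tr_idx], config, tcfg)
    sc <- predict(fit, images[te_idx])
    res[[f]] <- data.frame(image_index = te_idx, score = sc,
                           patient_id = patient_ids[te_idx],
                           label = labels[te_idx], partition = fn)
    hists[[fn]] <- fit$history
  }
  image_scores <- do.call(rbind, res)
  pt <- aggregate_patient_scores(image_scores$score, image_scores$patient_id)
  plab <- tapply(image_scores$label, image_scores$patient_id, max)
  ppart <- tapply(image_scores$partition, image_scores$patient_id, `[`, 1)
  pt$label <- as.integer(plab[pt$patient_id])
  pt$partition <- as.character(ppart[pt$patient_id])
  structure(list(patient_scores = pt, image_scores = image_scores,
                 histories = hists, config = config, train = train),
            class = "hecnn_cv")
}

#' @export
print.hecnn_cv <- function(x, ...) {
  k <- length(x$histories)
  cat(sprintf("%d-fold patient-level cross-validation: %d patients scored\n",
              k, nrow(x$patient_scores)))
  if (length(unique(x$patient_scores$label)) == 2)
    cat(sprintf("  CV AUC %.3f\n",
                roc_auc(x$patient_scores$score, x$patient_scores$label)))
  invisible(x)
}

#' Tune the low/high prediction-score operating threshold
#'
#' Among thresholds achieving sensitivity >= `min_sensitivity` on the
#' cross-validation patient scores, returns the one maximising the low-PS
#' fraction (ties resolved toward the lower threshold).  Patients score
#' low-PS when `score < threshold`.  When no threshold reaches the floor the
#' minimal observed score is returned with a warning.  The shipped defaults
#' used without tuning are 0.5 (PD-L1) and 0.28 (PD-1).
#'
#' @param scores patient-level CV scores.
#' @param labels integer 0/1 patient labels.
#' @param min_sensitivity sensitivity floor.
#' @return the threshold, with attributes `sensitivity` and
#'   `low_ps_fraction` at that threshold.
#' @export
tune_threshold <- function(scores, labels, min_sensitivity = 0.9) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stopf("both classes required to tune a threshold")
  cand <- sort(unique(c(0, scores)))
  n_pos <- sum(labels == 1)
  best <- NULL
  for (tau in cand) {
    sens <- sum(labels == 1 & scores >= tau) / n_pos
    lowf <- mean(scores < tau)
    if (sens >= min_sensitivity && (is.null(best) || lowf > best$lowf))
      best <- list(tau = tau, sens = sens, lowf = lowf)
  }
  if (is.null(best)) {
    warning("no threshold reaches the sensitivity floor; returning the minimal score")
    tau <- min(scores)
    best <- list(tau = tau, sens = sum(labels == 1 & scores >= tau) / n_pos,
                 lowf = mean(scores < tau))
  }
  structure(best$tau, sensitivity = best$sens, low_ps_fraction = best$lowf)
}

#' Accuracy-optimal threshold on training scores
#'
#' Sweeps observed scores and returns the threshold maximising accuracy of
#' the `score >= threshold` positivity rule (lower threshold on ties).
#'
#' @inheritParams tune_threshold
#' @return the threshold, with attribute `accuracy`.
#' @export
tune_threshold_accuracy <- function(scores, labels) {
  labels <- as.integer(labels)
  cand <- sort(unique(c(0, scores, max(scores) + 1e-9)))
  acc <- vapply(cand, function(tau)
    mean((scores >= tau) == (labels == 1)), 0)
  i <- which.max(acc)
  structure(cand[i], accuracy = acc[i])
}

#' Save / load a model checkpoint
#'
#' The checkpoint is the fitted `hecnn` object itself (weights, BatchNorm
#' statistics, architecture and training configs, operating threshold, seed,
#' format version), written with `saveRDS`; `predict` runs from a loaded
#' checkpoint alone.
#'
#' @param object a fitted `hecnn`.
#' @param path file path.
#' @return `path` / the restored `hecnn` object.
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "hecnn"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "hecnn") || !identical(obj$version, "hecnn-1"))
    stopf("not a compatible checkpoint: %s", path)
  obj
}
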