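# Transfer-learning calibration to an external cohort: fine-tune only the
# 256x2 (embedding x 2) linear head on a held-out calibration half, repeat,
# and average scores per patient.
#
# The backbone stays in eval mode with frozen weights and frozen BatchNorm
# statistics, so every image's embedding is fixed; head fine-tuning therefore
# runs on cached embeddings, which is mathematically identical to
# fine-tuning the last layer of the full network.

head_scores <- function(emb, w, b) {
  logits <- emb %*% w + rep(b, each = nrow(emb))
  softmax_rows(logits)[, 2]
}

finetune_head <- function(emb, labels, w, b, epochs = 10, lr = 1e-4,
                          batch_size = 32, gamma = 3) {
  params <- list(w = w, b = b)
  if (epochs == 0) return(params)
  opt <- radam_state(params)
  n <- nrow(emb)
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      e <- emb[idx, , drop = FALSE]
      logits <- e %*% params$w + rep(params$b, each = nrow(e))
      probs <- softmax_rows(logits)
      dz <- focal_grad_logits(probs, labels[idx], gamma)
      gr <- list(w = t(e) %*% dz, b = colSums(dz))
      up <- radam_step(opt, params, gr, lr)
      params <- up$params; opt <- up$state
    }
  }
  params
}

#' Calibrate a trained model to an external cohort
#'
#' Repeats `n_repeats` times: split the external cohort 50/50 at the patient
#' level (stratified by label so both halves carry both classes), fine-tune
#' only the final linear head on the calibration half's images, and score the
#' test half.  Each patient's calibrated score is the mean of its scores over
#' the repeats in which it fell in the test half; a patient that by chance
#' never lands in a test half is reported unscored (`NA`) rather than
#' dropped.  All non-head parameters are bit-identical to the base model.
#'
#' @param object a fitted [hecnn()] model (the base checkpoint).
#' @param images list of the external cohort's core images.
#' @param labels integer 0/1 image labels.
#' @param patient_ids patient id per image.
#' @param n_repeats number of independent calibration repeats (5, as in the
#'   reference workflow).
#' @param seed RNG seed; repeat r uses `seed + r`.
#' @param epochs,lr,batch_size head fine-tuning schedule (RAdam, focal
#'   gamma taken from the model's training config).  The default trains the
#'   head to convergence: a 256 x 2 readout on a few hundred cached
#'   embeddings needs on the order of a thousand optimizer steps before it
#'   moves appreciably from its initialisation, and an under-trained head
#'   leaves the calibration a no-op.
#' @param embeddings optional precomputed image embeddings
#'   (`predict(object, images, type = "embedding")`); since the backbone is
#'   frozen they are identical across repeats and seeds, so callers looping
#'   over seeds can extract them once.
#' @return an object of class `hecnn_calibration`: `patient_scores`
#'   (patient_id, score, label, n_repeats_scored; `NA` score when never in a
#'   test half), per-repeat details, and the fine-tuned heads.
#' @export
calibrate_to_cohort <- function(object, images, labels, patient_ids,
                                n_repeats = 5, seed = 1, epochs = 200,
                                lr = 1e-3, batch_size = 32, embeddings = NULL) {
  stopifnot(inherits(object, "hecnn"))
  labels <- as.integer(labels)
  pts <- unique(patient_ids)
  plab <- vapply(split(labels, patient_ids)[pts], max, 0L)
  if (length(unique(plab)) < 2)
    stopf("external cohort must contain both classes")
  if (min(table(plab)) < 2 || length(pts) < 4)
    stopf("cohort too small for a 50/50 calibration split with both classes in each half")
  emb <- embeddings %||% predict(object, images, type = "embedding")
  if (nrow(emb) != length(patient_ids)) stopf("embeddings must align with patient_ids")
  gamma <- object$train$focal_gamma
  per_rep <- vector("list", n_repeats)
  heads <- vector("list", n_repeats)
  acc <- stats::setNames(rep(0, length(pts)), pts)
  cnt <- stats::setNames(rep(0L, length(pts)), pts)
  for (r in seq_len(n_repeats)) {
    with_seed(seed + r, {
      cal_pts <- unlist(lapply(split(pts, plab[pts]), function(g)
        sample(g, floor(length(g) / 2))), use.names = FALSE)
      test_pts <- setdiff(pts, cal_pts)
      cal_idx <- which(patient_ids %in% cal_pts)
      te_idx <- which(patient_ids %in% test_pts)
      hp <- finetune_head(emb[cal_idx, , drop = FALSE], labels[cal_idx],
                          object$net$params[["head.w"]],
                          object$net$params[["head.b"]],
                          epochs = epochs, lr = lr, batch_size = batch_size,
                          gamma = gamma)
      sc <- head_scores(emb[te_idx, , drop = FALSE], hp$w, hp$b)
      ps <- aggregate_patient_scores(sc, patient_ids[te_idx])
      acc[ps$patient_id] <- acc[ps$patient_id] + ps$score
      cnt[ps$patient_id] <- cnt[ps$patient_id] + 1L
      per_rep[[r]] <- data.frame(repeat_id = r, patient_id = ps$patient_id,
                                  score = ps$score)
      heads[[r]] <- hp
    })
  }
  out <- data.frame(patient_id = pts,
                    score = ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_),
                    label = as.integer(plab[pts]),
                    n_repeats_scored = as.integer(cnt), row.names = NULL)
  structure(list(patient_scores = out, repeats = do.call(rbind, per_rep),
                 heads = heads, base_threshold = object$threshold,
                 n_repeats = n_repeats, seed = seed),
            class = "hecnn_calibration")
}

#' @export
print.hecnn_calibration <- function(x, ...) {
  sc <- x$patient_scores
  cat(sprintf("Head-only calibration: %d repeats, %d patients (%d scored, %d never in a test half)\n",
              x$n_repeats, nrow(sc), sum(!is.na(sc$score)), sum(is.na(sc$score))))
  ok <- !is.na(sc$score)
  if (length(unique(sc$label[ok])) == 2)
    cat(sprintf("  calibrated AUC %.3f\n", roc_auc(sc$score[ok], sc$label[ok])))
  invisible(x)
}

#' Non-head parameters of a model (freezing audit)
#'
#' Returns every trainable array except the linear head, for bit-identity
#' comparison before/after calibration.
#'
#' @param object an `hecnn` model or `hecnn_net`.
#' @return named list of parameter arrays.
#' @export
backbone_parameters <- function(object) {
  net <- if (inherits(object, "hecnn")) object$net else object
  net$params[setdiff(names(net$params), c("head.w", "head.b"))]
}
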