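# Patient-level feature extraction and 2-D stochastic neighbor embedding of
# the CNN feature space.
#
# No t-SNE implementation ships with this R stack, so `embed_2d` is an exact
# (O(n^2) per iteration) t-SNE: Gaussian input kernel with per-point
# bandwidths found by binary search on the perplexity, Student-t output
# kernel, gradient descent with momentum and early exaggeration.  Exact
# t-SNE is entirely adequate at cohort scale (hundreds of patients).

#' Extract one feature vector per patient
#'
#' Each patient is represented by the pre-head embedding of its
#' highest-scoring H&E image (the same image whose score becomes the patient
#' score under max aggregation).  Deterministic given the model.
#'
#' @param object a fitted [hecnn()] model.
#' @param images list of core images.
#' @param patient_ids patient id per image.
#' @param scores optional precomputed image scores (recomputed when `NULL`).
#' @return list with `features` (patients x embedding_dim matrix, rownames =
#'   patient ids), `scores` (named patient scores), and `patient_ids`.
#' @export
extract_patient_features <- function(object, images, patient_ids, scores = NULL) {
  if (is.null(scores)) scores <- predict(object, images)
  if (any(is.na(scores))) stopf("unscored images present")
  emb <- predict(object, images, type = "embedding")
  pts <- unique(patient_ids)
  sel <- vapply(pts, function(p) {
    ix <- which(patient_ids == p)
    ix[which.max(scores[ix])]
  }, 0L)
  feat <- emb[sel, , drop = FALSE]
  rownames(feat) <- pts
  ps <- vapply(pts, function(p) max(scores[patient_ids == p]), 0)
  list(features = feat, scores = stats::setNames(ps, pts), patient_ids = pts)
}

# Per-point Gaussian bandwidths matching log-perplexity by binary search.
tsne_input_probs <- function(D2, perplexity, tol = 1e-5) {
  n <- nrow(D2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - target) < tol) break
      if (H > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P
}

#' 2-D t-SNE embedding of feature vectors
#'
#' @param features numeric matrix, one row per patient.
#' @param seed RNG seed for the initial layout (fixed seed gives identical
#'   coordinates across runs).
#' @param perplexity target perplexity; capped at `(n - 1) / 3`.
#' @param n_iter gradient-descent iterations.
#' @param eta learning rate; `NULL` picks `max(50, n/12)` as in common
#'   implementations.
#' @return n x 2 coordinate matrix (rownames preserved).
#' @export
embed_2d <- function(features, seed = 1, perplexity = 30, n_iter = 750,
                     eta = NULL) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 4) stopf("too few points to embed (need >= 4, got %d)", n)
  perplexity <- max(2, min(perplexity, (n - 1) / 3))
  sq <- rowSums(X^2)
  D2 <- pmax(outer(sq, sq, "+") - 2 * X %*% t(X), 0)
  P <- tsne_input_probs(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_seed(seed, {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    exaggeration <- 12
    if (is.null(eta)) eta <- max(50, n / 12)
    for (iter in seq_len(n_iter)) {
      Pe <- if (iter <= 100) P * exaggeration else P
      ysq <- rowSums(Y^2)
      num <- 1 / (1 + pmax(outer(ysq, ysq, "+") - 2 * Y %*% t(Y), 0))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (Pe - Q) * num
      grad <- 4 * (diag(rowSums(W)) - W) %*% Y
      momentum <- if (iter <= 250) 0.5 else 0.8
      # adaptive per-coordinate gains, as in the reference implementation
      gains <- pmax(ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8), 0.01)
      dY <- momentum * dY - eta * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    rownames(Y) <- rownames(features)
    colnames(Y) <- c("tsne_1", "tsne_2")
    Y
  })
}

#' Render the patient map
#'
#' Scatter plot of the 2-D embedding colored by prediction score, with
#' flagged patients (e.g. system alerts) circled.
#'
#' @param coords n x 2 coordinates from [embed_2d()].
#' @param scores patient prediction scores, aligned with the rows.
#' @param flags optional logical vector marking alerted/discordant patients.
#' @param file optional PNG path; when `NULL`, draws on the active device.
#' @param palette color ramp for the score scale.
#' @return invisibly, the plotted data frame (x, y, score, flag).
#' @export
render_map <- function(coords, scores, flags = NULL, file = NULL,
                       palette = colorRampPalette(c("#20318c", "#b8b8c8", "#b2182b"))) {
  if (is.null(dim(coords)) || ncol(coords) != 2)
    stopf("coords must be an n x 2 matrix; run embed_2d first")
  if (nrow(coords) != length(scores)) stopf("scores must align with coords")
  flags <- flags %||% rep(FALSE, length(scores))
  df <- data.frame(x = coords[, 1], y = coords[, 2], score = scores, flag = flags)
  if (!is.null(file)) {
    png(file, width = 900, height = 800, res = 120)
    on.exit(dev.off())
  }
  sc_range <- range(scores)
  rel <- if (diff(sc_range) > 0) (scores - sc_range[1]) / diff(sc_range) else rep(0.5, length(scores))
  cols <- palette(101)[round(rel * 100) + 1]
  plot(df$x, df$y, pch = 19, col = cols, cex = 0.9,
       xlab = "t-SNE 1", ylab = "t-SNE 2",
       main = "Patient map of the CNN feature space")
  if (any(df$flag))
    points(df$x[df$flag], df$y[df$flag], pch = 1, cex = 1.8, lwd = 2, col = "black")
  legend("topright", bty = "n",
         legend = sprintf("score %.2f - %.2f", sc_range[1], sc_range[2]),
         pch = 19, col = palette(3)[2])
  invisible(df)
}
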