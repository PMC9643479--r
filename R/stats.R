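# Decision-support / quality-assurance statistics: low-PS / high-PS triage,
# confusion metrics, alert-coincidence probability, Cohen's kappa, ROC AUC
# with bootstrap confidence intervals, and screening curves.

#' Classify patients to low-PS / high-PS by the operating threshold
#'
#' `score < threshold` is low-PS (confidently negative); `score >= threshold`
#' is high-PS.  Equality goes to high-PS (documented tie-break).
#'
#' @param scores patient prediction scores in `[0, 1]`.
#' @param threshold operating threshold in `[0, 1]` (0.5 PD-L1 / 0.28 PD-1).
#' @return factor with levels `"low"`, `"high"`.
#' @export
classify_ps <- function(scores, threshold = 0.5) {
  factor(ifelse(scores >= threshold, "high", "low"), levels = c("low", "high"))
}

new_confusion_summary <- function(n, n_pos, n_lowPS, n_pos_in_lowPS) {
  stopifnot(n >= n_pos, n >= n_lowPS, n_pos >= n_pos_in_lowPS,
            n_lowPS >= n_pos_in_lowPS)
  npv <- if (n_lowPS > 0) (n_lowPS - n_pos_in_lowPS) / n_lowPS else NA_real_
  sens <- if (n_pos > 0) (n_pos - n_pos_in_lowPS) / n_pos else NA_real_
  spec <- if (n - n_pos > 0) (n_lowPS - n_pos_in_lowPS) / (n - n_pos) else NA_real_
  tp <- n_pos - n_pos_in_lowPS; tn <- n_lowPS - n_pos_in_lowPS
  structure(list(
    n = as.integer(n), n_pos = as.integer(n_pos),
    n_lowPS = as.integer(n_lowPS),
    n_pos_in_lowPS = as.integer(n_pos_in_lowPS),
    NPV = npv, sensitivity = sens, specificity = spec,
    accuracy = (tp + tn) / n,
    lowPS_fraction = n_lowPS / n,
    pct_pos_in_lowPS = if (n_lowPS > 0) 100 * n_pos_in_lowPS / n_lowPS else NA_real_,
    pct_pos_in_highPS = if (n > n_lowPS) 100 * tp / (n - n_lowPS) else NA_real_),
    class = "confusion_summary")
}

#' Triage confusion metrics
#'
#' NPV = fraction of low-PS patients that are truly negative; sensitivity =
#' fraction of positives classified high-PS; specificity = fraction of
#' negatives classified low-PS; accuracy is that of the `high-PS = positive`
#' rule at this threshold.  All derived from the four integer counts, with
#' rounding left to report time.
#'
#' @param labels integer 0/1 (or logical) patient labels.
#' @param ps low/high classes from [classify_ps()].
#' @return a `confusion_summary`.
#' @export
confusion_metrics <- function(labels, ps) {
  labels <- as.integer(labels)
  if (length(labels) == 0) stopf("empty input")
  if (length(labels) != length(ps)) stopf("labels and classes must align")
  low <- ps == "low"
  new_confusion_summary(length(labels), sum(labels == 1), sum(low),
                        sum(low & labels == 1))
}

#' @rdname confusion_metrics
#' @param n,n_pos,n_lowPS,n_pos_in_lowPS the four triage counts (cohort
#'   size, positives, low-PS patients, positives within low-PS), e.g. as
#'   printed in a published performance table.
#' @export
confusion_from_counts <- function(n, n_pos, n_lowPS, n_pos_in_lowPS) {
  new_confusion_summary(n, n_pos, n_lowPS, n_pos_in_lowPS)
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("Triage of %d patients (%d positive): %d low-PS (%.1f%%), %d high-PS\n",
              x$n, x$n_pos, x$n_lowPS, 100 * x$lowPS_fraction, x$n - x$n_lowPS))
  cat(sprintf("  NPV %.3f  sensitivity %.3f  specificity %.3f  accuracy %.3f\n",
              x$NPV, x$sensitivity, x$specificity, x$accuracy))
  cat(sprintf("  %% positive among low-PS %.1f%%, among high-PS %.1f%%\n",
              x$pct_pos_in_lowPS, x$pct_pos_in_highPS))
  invisible(x)
}

#' Probability that all system alerts fall on discordant cases by chance
#'
#' An alert is a case called positive by the pathologist but low-PS by the
#' model.  If alerts were uninformative draws without replacement from the
#' `n_pos` pathologist-positive cases, of which `n_discordant` are discordant
#' between pathologists, the chance that all `n_alerts` alerts land on
#' discordant cases is the hypergeometric product
#' `prod_{i=0}^{a-1} (d - i) / (n - i)` — e.g. `4/23 * 3/22 = 2.37%`.
#'
#' @param n_pos pathologist-positive cases.
#' @param n_discordant discordant cases among them.
#' @param n_alerts alerts observed.
#' @return the probability (1 for zero alerts, the empty product).
#' @export
alert_coincidence_prob <- function(n_pos, n_discordant, n_alerts) {
  if (!(is_count(n_pos) && is_count(n_discordant) && is_count(n_alerts)))
    stopf("all arguments must be non-negative integers")
  if (n_alerts > n_discordant || n_discordant > n_pos)
    stopf("need 0 <= n_alerts <= n_discordant <= n_pos")
  if (n_alerts == 0) return(1)
  i <- 0:(n_alerts - 1)
  prod((n_discordant - i) / (n_pos - i))
}

#' Cohen's kappa for a 2x2 concordance matrix
#'
#' `(p_o - p_e) / (1 - p_e)` with marginal-product chance agreement.
#'
#' @param matrix 2x2 matrix of counts, rows = rater 1, columns = rater 2
#'   (`matrix[1,1]` both-negative, `matrix[2,2]` both-positive), or a length-4
#'   vector `c(both_neg, neg_pos, pos_neg, both_pos)` filled row-wise.
#' @return kappa in `[-1, 1]`; `NA` with a warning when the margins are
#'   degenerate (`p_e = 1`).
#' @export
cohens_kappa <- function(matrix) {
  m <- if (is.matrix(matrix)) matrix else base::matrix(matrix, 2, 2, byrow = TRUE)
  if (!all(dim(m) == c(2, 2)) || any(m < 0) || any(m != round(m)))
    stopf("need a 2x2 matrix of non-negative integer counts")
  n <- sum(m)
  if (n == 0) stopf("empty concordance matrix")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - pe) < .Machine$double.eps^0.5) {
    warning("degenerate margins: chance agreement is 1, kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' ROC area under the curve
#'
#' The Mann-Whitney pair statistic `P(score_pos > score_neg) + 0.5 P(tie)`,
#' computed from ranks; invariant under strictly monotone score transforms.
#'
#' @param scores numeric prediction scores.
#' @param labels integer 0/1 (or logical) labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stopf("scores and labels must align")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stopf("AUC undefined: need at least one positive and one negative")
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples the rows (patients) of `data` with replacement `B` times,
#' recomputes `metric` on each resample, and returns the percentile interval
#' of the resampled values.  Seeded and reproducible.
#'
#' @param metric function of one resampled `data` returning a scalar (may
#'   return `NA` on degenerate resamples, e.g. single-class AUC).
#' @param data data frame (resampled by row) or vector.
#' @param B bootstrap replicates, >= 100.
#' @param seed RNG seed.
#' @param level confidence level.
#' @return named numeric `c(lower, upper)`, with attribute `point` (the
#'   metric on the full data).
#' @export
bootstrap_ci <- function(metric, data, B = 2000, seed = 1, level = 0.95) {
  if (B < 100) stopf("B must be >= 100")
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n == 0) stopf("empty data")
  take <- if (is.data.frame(data)) function(i) data[i, , drop = FALSE]
          else function(i) data[i]
  point <- metric(data)
  with_seed(seed, {
    vals <- vapply(seq_len(B), function(b) {
      v <- tryCatch(metric(take(sample.int(n, n, replace = TRUE))),
                    error = function(e) NA_real_)
      if (length(v) != 1) NA_real_ else as.numeric(v)
    }, 0)
    if (mean(is.na(vals)) > 0.5)
      stopf("metric undefined on more than half of the bootstrap resamples")
    qs <- stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE, names = FALSE)
    structure(c(lower = qs[1], upper = qs[2]), point = point)
  })
}

#' Screening curves over the threshold sweep
#'
#' Sweeps the operating threshold over the observed score values and returns
#' the four curves: ROC (sensitivity vs specificity), precision-recall,
#' NPV vs specificity, and sensitivity vs low-PS fraction.  Every curve point
#' equals the confusion metrics recomputed at that threshold.
#'
#' @param scores patient prediction scores.
#' @param labels integer 0/1 patient labels.
#' @return an object of class `screening_curves`: a data frame with columns
#'   `threshold`, `sensitivity`, `specificity`, `precision`, `recall`,
#'   `NPV`, `lowPS_fraction`, plus the `auc`.
#' @export
screening_curves <- function(scores, labels) {
  labels <- as.integer(labels)
  auc <- roc_auc(scores, labels)  # also validates both classes present
  taus <- c(sort(unique(scores)), max(scores) + 1e-9)
  rows <- lapply(taus, function(tau) {
    cm <- confusion_metrics(labels, classify_ps(scores, tau))
    tp <- cm$n_pos - cm$n_pos_in_lowPS
    n_high <- cm$n - cm$n_lowPS
    data.frame(threshold = tau, sensitivity = cm$sensitivity,
               specificity = cm$specificity,
               precision = if (n_high > 0) tp / n_high else NA_real_,
               recall = cm$sensitivity, NPV = cm$NPV,
               lowPS_fraction = cm$lowPS_fraction)
  })
  out <- do.call(rbind, rows)
  structure(list(sweep = out, auc = auc, n = length(labels)),
            class = "screening_curves")
}

#' @export
print.screening_curves <- function(x, ...) {
  cat(sprintf("Screening threshold sweep over %d thresholds (n = %d, AUC %.3f)\n",
              nrow(x$sweep), x$n, x$auc))
  invisible(x)
}

#' @export
plot.screening_curves <- function(x, ...) {
  s <- x$sweep
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(s$specificity, s$sensitivity, type = "l", xlim = c(1, 0),
       xlab = "Specificity", ylab = "Sensitivity",
       main = sprintf("ROC (AUC %.3f)", x$auc))
  plot(s$recall, s$precision, type = "l", xlab = "Recall (sensitivity)",
       ylab = "Precision (PPV)", main = "Precision-recall")
  plot(s$specificity, s$NPV, type = "l", xlab = "Specificity", ylab = "NPV",
       main = "NPV vs specificity")
  plot(s$lowPS_fraction, s$sensitivity, type = "l",
       xlab = "Fraction classified low-PS", ylab = "Sensitivity",
       main = "Sensitivity vs low-PS fraction")
  invisible(x)
}

#' Full evaluation report for a scored cohort
#'
#' AUC with a patient-level percentile-bootstrap confidence interval, the
#' triage confusion summary at the operating threshold, and the screening
#' curves.
#'
#' @param scores patient prediction scores.
#' @param labels integer 0/1 patient labels.
#' @param threshold operating threshold.
#' @param B bootstrap replicates.
#' @param seed bootstrap seed.
#' @return an object of class `eval_report`.
#' @export
eval_report <- function(scores, labels, threshold = 0.5, B = 2000, seed = 1) {
  labels <- as.integer(labels)
  df <- data.frame(score = scores, label = labels)
  ci <- bootstrap_ci(function(d) {
    if (length(unique(d$label)) < 2) return(NA_real_)
    roc_auc(d$score, d$label)
  }, df, B = B, seed = seed)
  structure(list(auc = roc_auc(scores, labels), auc_ci = ci,
                 confusion = confusion_metrics(labels, classify_ps(scores, threshold)),
                 curves = screening_curves(scores, labels),
                 threshold = threshold, B = B),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("AUC %.3f (%d%% CI %.3f - %.3f, %d bootstrap resamples)\n",
              x$auc, 95, x$auc_ci[["lower"]], x$auc_ci[["upper"]], x$B))
  cat(sprintf("Operating threshold %.2f:\n", x$threshold))
  print(x$confusion)
  invisible(x)
}
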