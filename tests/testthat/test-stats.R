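test_that("the threshold rule is binary, exhaustive, and ties go high", {
  expect_identical(as.character(classify_ps(0.49, 0.5)), "low")
  expect_identical(as.character(classify_ps(0.50, 0.5)), "high")
  set.seed(17)
  sc <- runif(1000)
  cls <- classify_ps(sc, 0.5)
  # brute-force comparison loop
  manual <- character(1000)
  for (i in 1:1000) manual[i] <- if (sc[i] >= 0.5) "high" else "low"
  expect_identical(as.character(cls), manual)
})

test_that("confusion metrics reproduce published triage statistics from their counts", {
  # 860 test patients, 140 positive, 473 low-PS of which 8 positive
  cm <- confusion_from_counts(860, 140, 473, 8)
  expect_equal(round(cm$NPV, 3), 0.983)
  expect_equal(round(cm$sensitivity, 3), 0.943)
  expect_equal(round(cm$specificity, 3), 0.646)
  # perfect triage
  perfect <- confusion_metrics(c(0, 0, 1, 1),
                               factor(c("low", "low", "high", "high"),
                                      levels = c("low", "high")))
  expect_identical(perfect$NPV, 1)
  expect_identical(perfect$sensitivity, 1)
  expect_identical(perfect$specificity, 1)
  expect_identical(perfect$accuracy, 1)
  # identity invariants hold exactly on integer counts
  expect_identical(cm$n_lowPS - cm$n_pos_in_lowPS, 465L)
  expect_error(confusion_metrics(integer(0), factor(character(0))), "empty")
})

test_that("confusion metrics agree with hand tabulation on random tables", {
  set.seed(18)
  for (rep in 1:5) {
    lab <- rbinom(50, 1, 0.3)
    sc <- runif(50)
    cm <- confusion_metrics(lab, classify_ps(sc, 0.5))
    # enumeration oracle
    tp <- 0; fn <- 0; tn <- 0; fp <- 0
    for (i in 1:50) {
      if (lab[i] == 1 && sc[i] >= 0.5) tp <- tp + 1
      if (lab[i] == 1 && sc[i] < 0.5) fn <- fn + 1
      if (lab[i] == 0 && sc[i] < 0.5) tn <- tn + 1
      if (lab[i] == 0 && sc[i] >= 0.5) fp <- fp + 1
    }
    expect_identical(cm$n_pos_in_lowPS, as.integer(fn))
    expect_equal(cm$NPV, tn / (tn + fn))
    expect_equal(cm$sensitivity, tp / (tp + fn))
    expect_equal(cm$specificity, tn / (tn + fp))
    expect_equal(cm$accuracy, (tp + tn) / 50)
  }
})

test_that("the alert-coincidence probability equals the hypergeometric enumeration", {
  # 2 alerts among 23 positives, 4 discordant: 4/23 * 3/22
  expect_equal(alert_coincidence_prob(23, 4, 2), (4 / 23) * (3 / 22))
  expect_equal(round(100 * alert_coincidence_prob(23, 4, 2), 2), 2.37)
  expect_identical(alert_coincidence_prob(10, 3, 0), 1)
  # exhaustive enumeration of all C(10, 2) draws
  draws <- combn(10, 2)
  all_disc <- mean(apply(draws, 2, function(d) all(d <= 3)))
  expect_equal(alert_coincidence_prob(10, 3, 2), all_disc, tolerance = 1e-12)
  # closed-form cross-check and monotone decrease in the alert count
  expect_equal(alert_coincidence_prob(10, 3, 2), choose(3, 2) / choose(10, 2))
  p <- vapply(0:3, function(a) alert_coincidence_prob(10, 3, a), 0)
  expect_true(all(diff(p) < 0))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(alert_coincidence_prob(10, 12, 2), "<=")
  expect_error(alert_coincidence_prob(10, 3, 4), "<=")
})

test_that("Cohen's kappa matches its definition on worked examples", {
  # two raters over 275 cases: 246 both-negative, 6 neg/pos, 4 pos/neg,
  # 19 both-positive
  m <- matrix(c(246, 6, 4, 19), 2, 2, byrow = TRUE)
  expect_equal(round(cohens_kappa(m), 3), 0.772)
  expect_equal(cohens_kappa(c(246, 6, 4, 19)), cohens_kappa(m))
  # independent arithmetic oracle
  po <- (246 + 19) / 275
  pe <- (252 * 250 + 23 * 25) / 275^2
  expect_equal(cohens_kappa(m), (po - pe) / (1 - pe), tolerance = 1e-12)
  expect_identical(cohens_kappa(matrix(c(30, 0, 0, 12), 2)), 1)
  expect_equal(cohens_kappa(matrix(c(25, 25, 25, 25), 2)), 0)
  expect_warning(k <- cohens_kappa(matrix(c(40, 0, 0, 0), 2)), "degenerate")
  expect_true(is.na(k))
  # kappa stays within [-1, 1] on random tables
  set.seed(19)
  for (i in 1:20) {
    mm <- matrix(rpois(4, 20), 2)
    if (sum(mm) == 0) next
    k <- suppressWarnings(cohens_kappa(mm))
    if (!is.na(k)) expect_true(k >= -1 && k <= 1)
  }
})

test_that("ROC AUC equals exhaustive pair counting and is monotone-invariant", {
  sc <- c(0.1, 0.4, 0.35, 0.8, 0.65, 0.8)
  lab <- c(0, 0, 1, 1, 0, 1)
  # exhaustive pair-counting oracle
  num <- 0
  for (i in which(lab == 1)) for (j in which(lab == 0)) {
    num <- num + (sc[i] > sc[j]) + 0.5 * (sc[i] == sc[j])
  }
  expect_equal(roc_auc(sc, lab), num / (sum(lab == 1) * sum(lab == 0)),
               tolerance = 1e-12)
  expect_identical(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  # labels independent of scores: AUC ~ 0.5
  set.seed(20)
  s2 <- runif(2000); l2 <- rbinom(2000, 1, 0.5)
  expect_lt(abs(roc_auc(s2, l2) - 0.5), 0.03)
  # invariance under strictly monotone transforms
  expect_equal(roc_auc(qlogis(pmin(pmax(sc, 1e-6), 1 - 1e-6)), lab),
               roc_auc(sc, lab))
  expect_error(roc_auc(sc, rep(1, 6)), "undefined")
})

test_that("bootstrap intervals are seeded, degenerate-safe, and calibrated", {
  df <- data.frame(x = rnorm(30))
  ci1 <- bootstrap_ci(function(d) mean(d$x), df, B = 200, seed = 7)
  ci2 <- bootstrap_ci(function(d) mean(d$x), df, B = 200, seed = 7)
  expect_identical(ci1, ci2)
  expect_lte(ci1[["lower"]], attr(ci1, "point"))
  expect_gte(ci1[["upper"]], attr(ci1, "point"))
  # constant metric gives a zero-width interval
  cc <- bootstrap_ci(function(d) 1.5, df, B = 100, seed = 1)
  expect_identical(unname(cc[1]), unname(cc[2]))
  expect_error(bootstrap_ci(function(d) mean(d$x), df, B = 50), "B")
  expect_error(bootstrap_ci(function(d) NA_real_, df, B = 100, seed = 1),
               "undefined")
  # coverage of a known mean ~ 95% over simulation replicates
  set.seed(21)
  hits <- 0; n_rep <- 400
  for (i in 1:n_rep) {
    x <- rnorm(40, mean = 2)
    ci <- bootstrap_ci(function(d) mean(d), x, B = 200, seed = i)
    if (ci[["lower"]] <= 2 && 2 <= ci[["upper"]]) hits <- hits + 1
  }
  expect_gt(hits / n_rep, 0.88)
  expect_lte(hits / n_rep, 0.99)
})

test_that("screening curves agree with confusion metrics at every threshold", {
  set.seed(22)
  sc <- round(runif(80), 2)
  lab <- rbinom(80, 1, 0.3)
  curves <- screening_curves(sc, lab)
  s <- curves$sweep
  # cross-check a handful of thresholds with direct sums
  for (tau in s$threshold[c(1, 10, 40, nrow(s))]) {
    low <- sc < tau
    expect_equal(s$sensitivity[s$threshold == tau],
                 sum(lab == 1 & !low) / sum(lab == 1))
    expect_equal(s$NPV[s$threshold == tau],
                 if (any(low)) sum(lab == 0 & low) / sum(low) else NA_real_)
    expect_equal(s$lowPS_fraction[s$threshold == tau], mean(low))
  }
  # sensitivity is non-increasing in the low-PS fraction; starts at 1
  ord <- order(s$lowPS_fraction)
  expect_true(all(diff(s$sensitivity[ord]) <= 1e-12))
  expect_identical(s$sensitivity[s$lowPS_fraction == 0], 1)
  expect_equal(curves$auc, roc_auc(sc, lab))
})

test_that("the evaluation report bundles AUC, CI, confusion, and curves", {
  set.seed(23)
  sc <- runif(60); lab <- rbinom(60, 1, 0.4)
  rep <- eval_report(sc, lab, threshold = 0.5, B = 200, seed = 2)
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$auc, roc_auc(sc, lab))
  expect_lte(rep$auc_ci[["lower"]], rep$auc)
  expect_gte(rep$auc_ci[["upper"]], rep$auc)
  expect_identical(rep$confusion$n, 60L)
  expect_output(print(rep), "AUC")
})
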