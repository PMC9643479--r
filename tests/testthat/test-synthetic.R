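test_that("cohort generation is byte-identical under a fixed seed and differs across seeds", {
  cc <- cohort_config(10, prevalence = 0.3, images_per_patient = c(1, 2),
                      image_size = c(64, 64), seed = 7)
  mp <- morphology_params(effect_size = 2)
  a <- generate_cohort(cc, mp)
  b <- generate_cohort(cc, mp)
  expect_identical(a, b)
  cc2 <- cc; cc2$seed <- 8L
  d <- generate_cohort(cc2, mp)
  expect_false(identical(a$images, d$images))
})

test_that("label frequency matches the configured prevalence", {
  # 16.5% positives at n = 1000: binomial 95% band
  coh <- generate_cohort(cohort_config(1000, prevalence = 0.165, seed = 5),
                         morphology_params(), render = FALSE)
  npos <- sum(coh$truth$label == "Positive")
  expect_gte(npos, 142)
  expect_lte(npos, 188)
  # law of large numbers at n = 5000, 3 binomial SDs
  coh2 <- generate_cohort(cohort_config(5000, prevalence = 0.165, seed = 6),
                          morphology_params(), render = FALSE)
  p_hat <- mean(coh2$truth$label == "Positive")
  expect_lt(abs(p_hat - 0.165), 3 * sqrt(0.165 * 0.835 / 5000))
})

test_that("zero effect size removes the class signal from the pixels", {
  coh <- tiny_cohort(n = 50, effect_size = 0, seed = 2, prevalence = 0.5)
  ann <- coh$annotations
  lab <- ann$label_or_exclusion
  means <- vapply(coh$images[ann$image_id], mean, 0)
  ncount <- vapply(coh$images[ann$image_id],
                   function(im) nrow(attr(im, "nuclei")), 0)
  expect_lt(abs(mean(means[lab == "Positive"]) - mean(means[lab == "Negative"])), 3e-3)
  # nucleus counts: identical generative rate for both classes
  expect_lt(abs(mean(ncount[lab == "Positive"]) / mean(ncount[lab == "Negative"]) - 1), 0.25)
})

test_that("cohort stain shift scales the channel means", {
  truth <- list(label = "Negative", latent = 0.2)
  mp <- morphology_params()
  set.seed(31); a <- render_tissue_image(truth, mp, c(1, 1, 1), c(64, 64))
  set.seed(31); b <- render_tissue_image(truth, mp, c(0.9, 1, 1.1), c(64, 64))
  expect_lt(mean(b[, , 1]), mean(a[, , 1]))
  expect_gt(mean(b[, , 3]), mean(a[, , 3]))
  expect_equal(dim(a), c(64, 64, 3))
  expect_true(all(a >= 0 & a <= 1))
})

test_that("zero immune-dot rate yields empty ground-truth dot lists", {
  mp <- morphology_params(immune_dot_rate_neg = 0, immune_dot_rate_pos = 0,
                          effect_size = 2)
  set.seed(4)
  for (z in c(-1, 0, 2)) {
    im <- render_tissue_image(list(label = "Positive", latent = z), mp,
                              image_size = c(64, 64))
    expect_identical(nrow(attr(im, "dots")), 0L)
  }
})

test_that("doubled positive nucleus density doubles the mean rendered count", {
  # latent values stratified over each class distribution (N(0,1) vs N(1,1))
  # so only Poisson rendering noise remains; the log-linear rate link makes
  # the expected count ratio exactly 2.
  mp <- morphology_params(nucleus_density_neg = 40, nucleus_density_pos = 80,
                          effect_size = 1)
  zq <- qnorm(ppoints(100))
  count_at <- function(z, lab) {
    im <- render_tissue_image(list(label = lab, latent = z), mp,
                              image_size = c(96, 96))
    nrow(attr(im, "nuclei"))
  }
  set.seed(11)
  n_neg <- vapply(zq, count_at, 0, lab = "Negative")
  n_pos <- vapply(zq + 1, count_at, 0, lab = "Positive")
  ratio <- mean(n_pos) / mean(n_neg)
  expect_gt(ratio, 2 * 0.9)
  expect_lt(ratio, 2 * 1.1)
})

test_that("excluded-category patients carry the matching rendered defect", {
  cc <- cohort_config(60, prevalence = 0.3, images_per_patient = c(1, 1),
                      image_size = c(64, 64), seed = 9,
                      exclusion_rates = c(NoTMA = 0.1, NoTissue = 0.1,
                                          OutOfFocus = 0.1, DeficientStaining = 0.1))
  coh <- generate_cohort(cc, morphology_params())
  pats <- coh$patients
  # NoTMA patients have no images at all
  expect_true(all(pats$n_images[pats$label_or_exclusion == "NoTMA"] == 0))
  by_cat <- split(coh$annotations$image_id, coh$annotations$label_or_exclusion)
  img_of <- function(cat) coh$images[[by_cat[[cat]][1]]]
  ref <- img_of("Negative")
  # blank disc: no nuclei rendered
  if (!is.null(by_cat$NoTissue))
    expect_identical(nrow(attr(img_of("NoTissue"), "nuclei")), 0L)
  # blur: strongly reduced local contrast
  if (!is.null(by_cat$OutOfFocus)) {
    gx <- function(im) mean(abs(diff(im[, , 1])))
    expect_lt(gx(img_of("OutOfFocus")), 0.5 * gx(ref))
  }
  # washed-out staining: higher brightness, lower spread
  if (!is.null(by_cat$DeficientStaining)) {
    ds <- img_of("DeficientStaining")
    expect_gt(mean(ds), mean(ref))
    expect_lt(sd(ds), sd(ref))
  }
})

test_that("generator rejects invalid configurations", {
  expect_error(cohort_config(0), "n_patients")
  expect_error(cohort_config(10, prevalence = 1.2), "prevalence")
  expect_error(cohort_config(10, images_per_patient = c(0, 2)), "images_per_patient")
  expect_error(cohort_config(10, exclusion_rates = c(NoTMA = 0.6, NoTissue = 0.5)),
               "exclusion_rates")
  expect_error(render_tissue_image(list(label = "Negative", latent = 0),
                                   morphology_params(), image_size = c(0, 64)),
               "positive")
  expect_error(render_tissue_image(list(label = "Negative", latent = 0),
                                   morphology_params(), image_size = c(32, 32)),
               "64")
  expect_error(morphology_params(effect_size = -1), "effect_size")
  expect_error(morphology_params(nucleus_density_neg = -5), "rates")
})

test_that("effect_size zero forces identical positive and negative parameter sets", {
  mp <- morphology_params(nucleus_density_neg = 30, nucleus_density_pos = 90,
                          effect_size = 0)
  expect_identical(mp$neg$nucleus_density, mp$pos$nucleus_density)
  expect_identical(mp$neg$stroma_anisotropy, mp$pos$stroma_anisotropy)
})

test_that("oracle AUC matches exhaustive pair counting and the binormal closed form", {
  # brute-force pair-counting oracle, written independently of the package
  pair_auc <- function(latent, pos) {
    s <- 0; np <- sum(pos); nn <- sum(!pos)
    for (i in which(pos)) {
      s <- s + sum(latent[i] > latent[!pos]) + 0.5 * sum(latent[i] == latent[!pos])
    }
    s / (np * nn)
  }
  set.seed(8)
  lat <- c(rnorm(300), rnorm(300, 1))
  truth <- data.frame(patient_id = seq_along(lat),
                      label = rep(c("Negative", "Positive"), each = 300),
                      latent = lat)
  expect_equal(oracle_auc(truth), pair_auc(lat, truth$label == "Positive"),
               tolerance = 1e-12)
  # Normal(0,1) vs Normal(1,1): AUC -> pnorm(1/sqrt(2)) ~ 0.760
  set.seed(9)
  big <- data.frame(patient_id = 1:4000,
                    label = rep(c("Negative", "Positive"), each = 2000),
                    latent = c(rnorm(2000), rnorm(2000, 1)))
  expect_equal(oracle_auc(big), pnorm(1 / sqrt(2)), tolerance = 0.03)
  expect_equal(oracle_auc_expected(1), pnorm(1 / sqrt(2)))
})

test_that("oracle AUC behaves at the edges and under monotone transforms", {
  sep <- data.frame(label = rep(c("Negative", "Positive"), each = 5),
                    latent = c(1:5, 11:15))
  expect_identical(oracle_auc(sep), 1)
  coh <- generate_cohort(cohort_config(500, prevalence = 0.5, seed = 3),
                         morphology_params(effect_size = 0), render = FALSE)
  expect_lt(abs(oracle_auc(coh$truth) - 0.5), 0.05)
  # invariance under strictly monotone transforms of the latent
  tr <- coh$truth
  for (f in list(exp, function(x) x^3, function(x) plogis(2 * x))) {
    tr2 <- tr; tr2$latent <- f(tr$latent)
    expect_equal(oracle_auc(tr2), oracle_auc(tr), tolerance = 1e-12)
  }
  one <- data.frame(label = rep("Negative", 4), latent = rnorm(4))
  expect_error(oracle_auc(one), "undefined")
})

test_that("cohort tables round-trip through disk", {
  coh <- tiny_cohort(n = 6, seed = 13, images = c(1, 2))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  ann <- read.csv(file.path(dir, "annotations.csv"))
  expect_setequal(ann$image_id[!is.na(ann$image_id)], names(coh$images))
  img_back <- read_image_png(ann$file_path[1])
  expect_equal(img_back, coh$images[[ann$image_id[1]]],
               ignore_attr = TRUE, tolerance = 1e-12)
})
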