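# Fixtures are generated in code: small synthetic cohorts and a tiny trained
# model shared (lazily, once per session) across test files.

tiny_cnn <- function() cnn_config(input_side = 32, stem_width = 4,
                                  block_widths = c(4, 4, 8, 8))

tiny_cohort <- function(n = 24, effect_size = 3, seed = 1, prevalence = 0.4,
                        side = 64, images = c(1, 1), ...) {
  generate_cohort(cohort_config(n, prevalence = prevalence,
                                images_per_patient = images,
                                image_size = c(side, side), seed = seed, ...),
                  morphology_params(effect_size = effect_size))
}

# Annotation table with the category counts of a large breast-cancer TMA
# cohort (one row per patient).
bcca_shaped_table <- function() {
  data.frame(
    patient_id = sprintf("P%04d", seq_len(4944)),
    label_or_exclusion = rep(c("Negative", "Positive", "NoTMA", "NoTissue",
                               "NoTumor", "DeficientStaining", "OutOfFocus"),
                             times = c(2819, 557, 168, 969, 176, 224, 31)),
    cohort = "BCCA")
}

# One tiny fitted model, trained on first use and reused across files.
.fit_cache <- new.env(parent = emptyenv())
tiny_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    coh <- tiny_cohort(n = 20, effect_size = 3, seed = 3, images = c(1, 2))
    td <- cohort_training_data(coh)
    .fit_cache$cohort <- coh
    .fit_cache$data <- td
    .fit_cache$fit <- hecnn(td$images, td$labels, tiny_cnn(),
                            train_config(epochs = 3, seed = 9))
  }
  .fit_cache$fit
}
tiny_fit_data <- function() {
  tiny_fit()
  list(cohort = .fit_cache$cohort, data = .fit_cache$data)
}
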