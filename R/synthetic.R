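# Synthetic TMA cohort generator
#
# Emulates single-core H&E tissue-microarray images with a planted,
# label-correlated morphological signal.  All label information reaches the
# pixels only through a per-patient latent scalar z (z ~ N(0,1) for negatives,
# N(effect_size, 1) for positives); rendered morphology parameters are
# deterministic functions of z.  This sufficiency property makes the
# pair-counting AUC of z itself (`oracle_auc`) an upper bound on the AUC any
# image model can achieve on the cohort.

#' Morphology parameters of the synthetic tissue renderer
#'
#' Class-conditional morphology of the planted signal.  Negative (low
#' prediction score) cases emulate dense streaming desmoplastic stroma:
#' coherently oriented texture, moderate cellularity, few immune-cell dots.
#' Positive cases emulate crowded solid tumor nests with abundant
#' tumor-associated immune cells: high nucleus density, many small dark dots,
#' little stromal orientation.
#'
#' `effect_size` scales the positive/negative separation twice over: the
#' effective positive parameter set is `neg + effect_size * (pos - neg)`, and
#' the per-patient latent means are 0 (negative) versus `effect_size`
#' (positive).  `effect_size = 0` therefore collapses the positive parameters
#' onto the negative ones and removes all label signal.
#'
#' @param nucleus_density_neg,nucleus_density_pos expected nuclei per
#'   10^4 px^2 of tissue disc.
#' @param immune_dot_rate_neg,immune_dot_rate_pos expected small-dark-dot
#'   count per image.
#' @param stroma_anisotropy_neg,stroma_anisotropy_pos orientation coherence of
#'   the stromal texture, in `[0, 1]`.
#' @param lumen_rate expected ring (gland lumen) structures per image.
#' @param effect_size non-negative scalar scaling the class separation.
#' @return an object of class `morphology_params`.
#' @export
morphology_params <- function(nucleus_density_neg = 40, nucleus_density_pos = 80,
                              immune_dot_rate_neg = 2, immune_dot_rate_pos = 12,
                              stroma_anisotropy_neg = 0.7, stroma_anisotropy_pos = 0.2,
                              lumen_rate = 1, effect_size = 1) {
  rates <- c(nucleus_density_neg, nucleus_density_pos,
             immune_dot_rate_neg, immune_dot_rate_pos, lumen_rate)
  if (any(!is.finite(rates)) || any(rates < 0))
    stopf("morphology rates must be finite and >= 0")
  if (stroma_anisotropy_neg < 0 || stroma_anisotropy_neg > 1 ||
      stroma_anisotropy_pos < 0 || stroma_anisotropy_pos > 1)
    stopf("stroma anisotropy must lie in [0, 1]")
  if (!is.finite(effect_size) || effect_size < 0)
    stopf("effect_size must be a finite non-negative scalar")
  neg <- list(nucleus_density = nucleus_density_neg,
              immune_dot_rate = immune_dot_rate_neg,
              stroma_anisotropy = stroma_anisotropy_neg)
  pos_raw <- list(nucleus_density = nucleus_density_pos,
                  immune_dot_rate = immune_dot_rate_pos,
                  stroma_anisotropy = stroma_anisotropy_pos)
  # effective positive parameters: separation scaled by effect_size
  pos <- list(
    nucleus_density = max(0, neg$nucleus_density +
                            effect_size * (pos_raw$nucleus_density - neg$nucleus_density)),
    immune_dot_rate = max(0, neg$immune_dot_rate +
                            effect_size * (pos_raw$immune_dot_rate - neg$immune_dot_rate)),
    stroma_anisotropy = min(1, max(0, neg$stroma_anisotropy +
                                     effect_size * (pos_raw$stroma_anisotropy - neg$stroma_anisotropy))))
  structure(list(neg = neg, pos = pos, pos_raw = pos_raw,
                 lumen_rate = lumen_rate, effect_size = effect_size),
            class = "morphology_params")
}

#' Synthetic cohort configuration
#'
#' @param n_patients number of patients to generate.
#' @param prevalence fraction of positive labels among included patients, in
#'   `[0, 1]`.
#' @param images_per_patient inclusive integer range `c(min, max)` of H&E
#'   images per patient (minimum >= 1).
#' @param image_size `c(height, width)` of rendered images in pixels; the
#'   default 256 x 256 is the desk-scale mode, `c(1440, 2256)` is the
#'   full-scanner-resolution mode.
#' @param stain_shift per-channel multiplicative RGB triple emulating
#'   cohort-specific staining/digitisation shifts.
#' @param exclusion_rates named fractions of patients carrying each
#'   non-diagnostic annotation category (`NoTMA`, `NoTissue`, `NoTumor`,
#'   `DeficientStaining`, `OutOfFocus`); must sum to < 1.
#' @param cohort cohort tag carried into the annotation table.
#' @param seed integer RNG seed; identical (config, morphology, seed) give
#'   byte-identical cohorts.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients, prevalence = 0.165,
                          images_per_patient = c(1, 3),
                          image_size = c(256, 256),
                          stain_shift = c(1, 1, 1),
                          exclusion_rates = c(NoTMA = 0, NoTissue = 0, NoTumor = 0,
                                              DeficientStaining = 0, OutOfFocus = 0),
                          cohort = "BCCA-like", seed = 1) {
  if (!is_count(n_patients) || n_patients < 1)
    stopf("n_patients must be a positive integer (empty cohorts are not allowed)")
  if (!is.numeric(prevalence) || prevalence < 0 || prevalence > 1)
    stopf("prevalence must lie in [0, 1]")
  if (length(images_per_patient) != 2 || images_per_patient[1] < 1 ||
      images_per_patient[2] < images_per_patient[1])
    stopf("images_per_patient must be an inclusive range c(min, max) with min >= 1")
  if (length(image_size) != 2 || any(image_size < 64))
    stopf("image_size must be c(height, width) with both >= 64")
  if (length(stain_shift) != 3 || any(stain_shift <= 0))
    stopf("stain_shift must be a positive RGB triple")
  known <- c("NoTMA", "NoTissue", "NoTumor", "DeficientStaining", "OutOfFocus")
  full <- stats::setNames(numeric(5), known)
  if (length(exclusion_rates)) {
    if (is.null(names(exclusion_rates)) || !all(names(exclusion_rates) %in% known))
      stopf("exclusion_rates must be named with categories among: %s",
            paste(known, collapse = ", "))
    full[names(exclusion_rates)] <- exclusion_rates
  }
  if (any(full < 0) || sum(full) >= 1)
    stopf("exclusion_rates must be non-negative and sum to < 1")
  structure(list(n_patients = as.integer(n_patients), prevalence = prevalence,
                 images_per_patient = as.integer(images_per_patient),
                 image_size = as.integer(image_size), stain_shift = stain_shift,
                 exclusion_rates = full, cohort = cohort, seed = as.integer(seed)),
            class = "cohort_config")
}

# Morphology parameters as functions of the per-patient latent z.
# Rates use a log-linear link, rate(z) = neg * exp(log(pos/neg)/es * z), so the
# ratio of class means is exactly pos/neg; degenerate cases fall back to a
# probit-interpolated linear link.
rate_from_latent <- function(neg, pos, es, z) {
  if (es <= 0 || isTRUE(all.equal(neg, pos))) return(rep(neg, length(z)))
  if (neg > 0 && pos > 0) neg * exp(log(pos / neg) / es * z)
  else pmax(0, neg + pnorm(z - es / 2) * (pos - neg))
}

mix_from_latent <- function(neg, pos, es, z) {
  if (es <= 0) return(rep(neg, length(z)))
  pmin(1, pmax(0, neg + pnorm(z - es / 2) * (pos - neg)))
}

latent_morphology <- function(morph, z) {
  list(nucleus_density = rate_from_latent(morph$neg$nucleus_density,
                                          morph$pos$nucleus_density,
                                          morph$effect_size, z),
       immune_dot_rate = rate_from_latent(morph$neg$immune_dot_rate,
                                          morph$pos$immune_dot_rate,
                                          morph$effect_size, z),
       stroma_anisotropy = mix_from_latent(morph$neg$stroma_anisotropy,
                                           morph$pos$stroma_anisotropy,
                                           morph$effect_size, z))
}

# Colors chosen to evoke H&E: eosin-pink tissue, hematoxylin-purple nuclei.
.he_colors <- list(background = c(0.960, 0.945, 0.960),
                   tissue = c(0.890, 0.720, 0.800),
                   nucleus = c(0.360, 0.220, 0.530),
                   dot = c(0.220, 0.130, 0.420),
                   lumen = c(0.985, 0.975, 0.985))

draw_blob <- function(img, x0, y0, rx, ry, theta, col, hardness = 1.4) {
  H <- dim(img)[1]; W <- dim(img)[2]
  r <- max(rx, ry)
  rows <- max(1, floor(y0 - r - 1)):min(H, ceiling(y0 + r + 1))
  cols <- max(1, floor(x0 - r - 1)):min(W, ceiling(x0 + r + 1))
  if (!length(rows) || !length(cols)) return(img)
  dy <- rows - y0; dx <- cols - x0
  DX <- matrix(dx, length(rows), length(cols), byrow = TRUE)
  DY <- matrix(dy, length(rows), length(cols))
  u <- (DX * cos(theta) + DY * sin(theta)) / rx
  v <- (-DX * sin(theta) + DY * cos(theta)) / ry
  alpha <- pmin(1, pmax(0, hardness - (u^2 + v^2))) * 0.92
  for (ch in 1:3)
    img[rows, cols, ch] <- img[rows, cols, ch] * (1 - alpha) + col[ch] * alpha
  img
}

#' Render one synthetic H&E tissue-core image
#'
#' Draws a circular 0.6-mm-style tissue disc on a light background: stromal
#' texture with latent-dependent orientation coherence, dark elliptical nuclei
#' at latent-dependent density, small dark immune-cell dots, and occasional
#' lumen rings.  Ground-truth object lists (nuclei, dots) are attached as
#' attributes so morphology claims are assertable without a detector.
#'
#' @param truth list or one-row data frame with elements `label`
#'   (`"Negative"`/`"Positive"`) and `latent` (the scalar z actually used to
#'   render).
#' @param morph a [morphology_params()] object.
#' @param cohort_shift per-channel multiplicative RGB triple.
#' @param image_size `c(height, width)`, both >= 64.
#' @param defect `NULL` for diagnostic tissue, or one of `"NoTissue"`
#'   (blank disc), `"NoTumor"` (stroma without tumor cellularity),
#'   `"DeficientStaining"` (washed-out stain), `"OutOfFocus"` (blurred).
#' @return numeric height x width x 3 array in `[0, 1]`, 8-bit quantised,
#'   with attributes `nuclei` (data frame x, y, rx, ry, theta), `dots`
#'   (data frame x, y), `defect`, and `latent`.
#' @export
render_tissue_image <- function(truth, morph, cohort_shift = c(1, 1, 1),
                                image_size = c(256, 256), defect = NULL) {
  if (length(image_size) != 2 || any(!is.finite(image_size)) || any(image_size <= 0))
    stopf("image_size must be two positive numbers")
  if (any(image_size < 64)) stopf("image_size must be at least 64 x 64")
  H <- as.integer(image_size[1]); W <- as.integer(image_size[2])
  z <- as.numeric(truth$latent)
  pars <- latent_morphology(morph, z)
  S <- min(H, W)

  cx <- (W + 1) / 2; cy <- (H + 1) / 2; R <- 0.45 * S
  X <- matrix(seq_len(W), H, W, byrow = TRUE)
  Y <- matrix(seq_len(H), H, W)
  disc <- (X - cx)^2 + (Y - cy)^2 <= R^2

  img <- array(0, c(H, W, 3))
  bg_noise <- matrix(rnorm(H * W, 0, 0.006), H, W)
  for (ch in 1:3) img[, , ch] <- .he_colors$background[ch] + bg_noise

  no_tissue <- !is.null(defect) && defect == "NoTissue"
  if (!no_tissue) {
    # stromal texture: coherent oriented waves mixed with isotropic waves
    aniso <- pars$stroma_anisotropy
    theta0 <- runif(1, 0, pi)
    phase <- runif(4, 0, 2 * pi)
    freq <- 9 / S
    orient <- sin(2 * pi * freq * (X * cos(theta0) + Y * sin(theta0)) + phase[1])
    iso_ang <- runif(3, 0, pi)
    iso <- (sin(2 * pi * freq * 1.31 * (X * cos(iso_ang[1]) + Y * sin(iso_ang[1])) + phase[2]) +
            sin(2 * pi * freq * 0.73 * (X * cos(iso_ang[2]) + Y * sin(iso_ang[2])) + phase[3]) +
            sin(2 * pi * freq * 1.87 * (X * cos(iso_ang[3]) + Y * sin(iso_ang[3])) + phase[4])) / sqrt(3)
    texture <- 0.07 * (aniso * orient + (1 - aniso) * iso)
    edge <- pmin(1, pmax(0, (R - sqrt((X - cx)^2 + (Y - cy)^2)) / 2))
    for (ch in 1:3) {
      tissue_val <- .he_colors$tissue[ch] * (1 + texture)
      img[, , ch] <- img[, , ch] * (1 - edge) + tissue_val * edge
    }

    no_tumor <- !is.null(defect) && defect == "NoTumor"
    dens <- if (no_tumor) 0.12 * pars$nucleus_density else pars$nucleus_density
    dot_rate <- if (no_tumor) 0 else pars$immune_dot_rate

    disc_area <- pi * R^2
    n_nuc <- rpois(1, dens * disc_area / 1e4)
    nuc_r <- max(1.5, 0.028 * R)
    nuclei <- data.frame(x = numeric(0), y = numeric(0), rx = numeric(0),
                         ry = numeric(0), theta = numeric(0))
    if (n_nuc > 0) {
      rr <- R * 0.96 * sqrt(runif(n_nuc)); aa <- runif(n_nuc, 0, 2 * pi)
      nuclei <- data.frame(x = cx + rr * cos(aa), y = cy + rr * sin(aa),
                           rx = nuc_r * runif(n_nuc, 0.8, 1.25),
                           ry = nuc_r * runif(n_nuc, 0.55, 1.0),
                           theta = runif(n_nuc, 0, pi))
      for (i in seq_len(n_nuc))
        img <- draw_blob(img, nuclei$x[i], nuclei$y[i], nuclei$rx[i],
                         nuclei$ry[i], nuclei$theta[i], .he_colors$nucleus)
    }

    n_dot <- rpois(1, dot_rate)
    dots <- data.frame(x = numeric(0), y = numeric(0))
    if (n_dot > 0) {
      rr <- R * 0.92 * sqrt(runif(n_dot)); aa <- runif(n_dot, 0, 2 * pi)
      dots <- data.frame(x = cx + rr * cos(aa), y = cy + rr * sin(aa))
      dr <- max(1.1, 0.016 * R)
      for (i in seq_len(n_dot))
        img <- draw_blob(img, dots$x[i], dots$y[i], dr, dr, 0, .he_colors$dot,
                         hardness = 1.2)
    }

    n_lum <- rpois(1, morph$lumen_rate)
    if (n_lum > 0) {
      rr <- R * 0.7 * sqrt(runif(n_lum)); aa <- runif(n_lum, 0, 2 * pi)
      for (i in seq_len(n_lum)) {
        lr <- R * runif(1, 0.08, 0.14)
        img <- draw_blob(img, cx + rr[i] * cos(aa[i]), cy + rr[i] * sin(aa[i]),
                         lr, lr, 0, .he_colors$lumen, hardness = 1.1)
      }
    }
  } else {
    nuclei <- data.frame(x = numeric(0), y = numeric(0), rx = numeric(0),
                         ry = numeric(0), theta = numeric(0))
    dots <- data.frame(x = numeric(0), y = numeric(0))
  }
  if (no_tissue) {
    dots <- data.frame(x = numeric(0), y = numeric(0))
  }

  if (!is.null(defect) && defect == "DeficientStaining") {
    gray <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
    for (ch in 1:3) img[, , ch] <- 0.25 * img[, , ch] + 0.75 * (0.4 * gray + 0.58)
  }
  if (!is.null(defect) && defect == "OutOfFocus")
    img <- as.array(EBImage::gblur(img, sigma = max(3, S / 28)))

  for (ch in 1:3) img[, , ch] <- img[, , ch] * cohort_shift[ch]
  img <- quantize8(img)
  attr(img, "nuclei") <- nuclei
  attr(img, "dots") <- dots
  attr(img, "defect") <- defect %||% "none"
  attr(img, "latent") <- z
  img
}

#' Generate a synthetic TMA cohort
#'
#' Draws patient labels at the configured prevalence, assigns non-diagnostic
#' exclusion categories at the configured rates (rendering the matching image
#' defect), draws each patient's latent morphology scalar, and renders 1-4
#' H&E core images per patient.  Identical `(config, morph)` (the seed lives
#' in the config) give byte-identical cohorts.
#'
#' @param config a [cohort_config()] object.
#' @param morph a [morphology_params()] object.
#' @param render if `FALSE`, skip image rendering and return only the
#'   tables (labels, latents, annotations) — useful for large-n statistical
#'   checks of the cohort-level machinery.
#' @return an object of class `he_cohort`: a list with elements
#'   `patients` (patient-level data frame), `annotations` (image-level data
#'   frame: patient_id, image_id, cohort, stain, label_or_exclusion),
#'   `images` (named list of rendered arrays with ground-truth attributes),
#'   `truth` (data frame patient_id, label, latent for included patients),
#'   plus the `config` and `morph` used.
#' @export
generate_cohort <- function(config, morph = morphology_params(), render = TRUE) {
  if (!inherits(config, "cohort_config")) stopf("config must be a cohort_config object")
  if (!inherits(morph, "morphology_params")) stopf("morph must be a morphology_params object")
  if (config$n_patients == 0) stopf("cannot generate an empty cohort (n_patients = 0)")
  with_seed(config$seed, {
    n <- config$n_patients
    excl <- config$exclusion_rates
    cats <- sample(c("Included", names(excl)), n, replace = TRUE,
                   prob = c(1 - sum(excl), excl))
    label <- ifelse(cats == "Included",
                    ifelse(rbinom(n, 1, config$prevalence) == 1, "Positive", "Negative"),
                    cats)
    z <- rnorm(n) + morph$effect_size * (label == "Positive")
    pid <- sprintf("%s_P%05d", gsub("[^A-Za-z0-9]", "", config$cohort), seq_len(n))
    n_img <- ifelse(cats == "NoTMA", 0L,
                    sample(seq(config$images_per_patient[1], config$images_per_patient[2]),
                           n, replace = TRUE))
    images <- list()
    ann <- vector("list", n)
    for (i in seq_len(n)) {
      if (n_img[i] == 0) next
      defect <- if (cats[i] %in% c("NoTissue", "NoTumor", "DeficientStaining", "OutOfFocus"))
        cats[i] else NULL
      if (render) {
        for (j in seq_len(n_img[i])) {
          iid <- sprintf("%s_img%d", pid[i], j)
          images[[iid]] <- render_tissue_image(
            list(label = label[i], latent = z[i]), morph,
            cohort_shift = config$stain_shift, image_size = config$image_size,
            defect = defect)
        }
      }
      ann[[i]] <- data.frame(patient_id = pid[i],
                             image_id = sprintf("%s_img%d", pid[i], seq_len(n_img[i])),
                             cohort = config$cohort, stain = "HE",
                             label_or_exclusion = label[i])
    }
    annotations <- do.call(rbind, c(ann[!vapply(ann, is.null, TRUE)],
                                    list(make.row.names = FALSE)))
    no_tma <- which(n_img == 0)
    if (length(no_tma)) {
      annotations <- rbind(annotations,
                           data.frame(patient_id = pid[no_tma], image_id = NA_character_,
                                      cohort = config$cohort, stain = "HE",
                                      label_or_exclusion = label[no_tma]))
    }
    patients <- data.frame(patient_id = pid, cohort = config$cohort,
                           label_or_exclusion = label, n_images = n_img)
    inc <- label %in% c("Negative", "Positive")
    truth <- data.frame(patient_id = pid[inc], label = label[inc], latent = z[inc])
    structure(list(patients = patients, annotations = annotations,
                   images = images, truth = truth, config = config, morph = morph),
              class = "he_cohort")
  })
}

#' @export
print.he_cohort <- function(x, ...) {
  cat(sprintf("Synthetic TMA cohort '%s': %d patients, %d images (%dx%d px)\n",
              x$config$cohort, nrow(x$patients), length(x$images),
              x$config$image_size[1], x$config$image_size[2]))
  cat(sprintf("  included %d (%d positive), excluded %d; effect size %.2f\n",
              nrow(x$truth), sum(x$truth$label == "Positive"),
              nrow(x$patients) - nrow(x$truth), x$morph$effect_size))
  invisible(x)
}

#' Write a cohort to disk as PNG images and CSV tables
#'
#' @param cohort an `he_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly; writes `annotations.csv` (with `file_path`
#'   column), `truth.csv`, and one PNG per image.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- cohort$annotations
  ann$file_path <- ifelse(is.na(ann$image_id), NA_character_,
                          file.path(dir, paste0(ann$image_id, ".png")))
  for (k in which(!is.na(ann$image_id)))
    write_image_png(cohort$images[[ann$image_id[k]]], ann$file_path[k])
  write.csv(ann, file.path(dir, "annotations.csv"), row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Training arrays and labels of the included patients of a cohort
#'
#' @param cohort an `he_cohort`.
#' @return list with `images` (list of arrays), `labels` (integer 0/1),
#'   `patient_ids` (character, aligned with `images`), and `patients`
#'   (the included patient ids).
#' @export
cohort_training_data <- function(cohort) {
  ann <- cohort$annotations
  keep <- ann$label_or_exclusion %in% c("Negative", "Positive") & !is.na(ann$image_id)
  ann <- ann[keep, , drop = FALSE]
  list(images = cohort$images[ann$image_id],
       labels = as.integer(ann$label_or_exclusion == "Positive"),
       patient_ids = ann$patient_id,
       patients = unique(ann$patient_id))
}

#' Best achievable AUC on a synthetic cohort
#'
#' Pair-counting (Mann-Whitney) AUC of the generator's latent morphology
#' scalar against the planted labels: `P(z_pos > z_neg) + 0.5 P(tie)`.  Since
#' images depend on labels only through the latent, this upper-bounds the AUC
#' of any model trained on the images.  Its large-sample expectation is
#' `pnorm(effect_size / sqrt(2))` (binormal, unit variances).
#'
#' @param truth data frame with columns `label`
#'   (`"Negative"`/`"Positive"`) and `latent`, as in `he_cohort$truth`.
#' @return the AUC, a scalar in `[0, 1]`.
#' @export
oracle_auc <- function(truth) {
  lab <- truth$label == "Positive"
  n_pos <- sum(lab); n_neg <- sum(!lab)
  if (n_pos == 0 || n_neg == 0)
    stopf("AUC undefined: need at least one positive and one negative")
  r <- rank(truth$latent)
  (sum(r[lab]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Expected oracle AUC for a given effect size
#'
#' Closed form for the binormal latent model with unit variances.
#'
#' @param effect_size separation of the latent class means.
#' @return `pnorm(effect_size / sqrt(2))`.
#' @export
oracle_auc_expected <- function(effect_size) pnorm(effect_size / sqrt(2))
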