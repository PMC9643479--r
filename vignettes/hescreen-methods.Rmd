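---
title: "Predicting immune-checkpoint status from H&E tissue-microarray images: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting immune-checkpoint status from H&E tissue-microarray images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hescreen)
```

## The problem

Immunohistochemical (IHC) scoring of PD-L1 (SP142, immune-cell score
IC ≥ 1%) and PD-1 (NAT105, combined positive score CPS ≥ 1%) defines which
breast-cancer patients are candidates for checkpoint immunotherapy, but the
stain is expensive, not always available, and its interpretation varies
between pathologists. `hescreen` implements a screening pipeline that
predicts a patient's PD-L1/PD-1 status from routine H&E-stained
tissue-microarray (TMA) core images alone, and a decision-support layer that
turns the continuous prediction score into a low-PS / high-PS triage:
low-PS patients are confidently negative (high negative predictive value),
so IHC staining and pathologist review can be concentrated on the high-PS
minority, and a pathologist-positive call on a low-PS patient becomes an
*alert* worth a second read.

The learning problem is weakly supervised: labels exist per patient, every
core image of a patient inherits that label, and the patient-level score is
the maximum over the patient's image scores (a patient is positive if any
of their cores looks positive).

## Pipeline

1. **Cohort assembly** (`load_annotations`, `apply_exclusions`): a CSV of
   per-patient (or per-image) annotations with the seven categories
   `Negative`, `Positive`, `No TMA`, `No tissue`, `No tumor`,
   `Deficient staining`, `Out of focus`; only the first two enter the
   analysis, and the accounting report reproduces the exclusion arithmetic
   (total = included + excluded, included = positives + negatives).
2. **Splits** (`split_train_test`, `make_cv_folds`): always at the patient
   level, so no image of a patient can leak across partitions
   (`audit_no_leakage` asserts this on every cross-validation run). The
   test-set size uses the *floor* rule, `floor(fraction * n)`: with 3376
   included patients and fraction 0.255 this gives the 860/2516 split of
   the motivating cohort. Folds are dealt round-robin over a shuffled
   patient order, so sizes differ by at most one (2516 patients in 5 folds:
   sizes 503/504).
3. **Preprocessing** (`center_crop`, `random_crop_train`,
   `resize_to_input`): inference deterministically center-crops the square
   short side (origin x = 408 on a 2256 x 1440 frame) and resizes to the
   network input; training draws the crop uniformly from a horizontally
   centered band (offsets 308-508 on the full frame) before resizing.
4. **Augmentation** (`augment`): training only, in the fixed order
   geometric (flip, rotation) → gamma → saturation → temperature → noise →
   blur, clipping back to [0, 1] after each color step.
5. **Model and training** (`hecnn`): a compact residual CNN trained with
   focal loss under RAdam; see below.
6. **Scoring** (`predict`, `aggregate_patient_scores`, `tune_threshold`):
   deterministic inference, per-patient maximum, and an operating threshold
   chosen on cross-validation scores to maximise the low-PS fraction
   subject to a sensitivity floor.
7. **Calibration** (`calibrate_to_cohort`): transfer to an external cohort
   by fine-tuning only the final linear head on a held-out calibration
   half, repeated five times with scores averaged per patient.
8. **Statistics and visualisation** (`confusion_metrics`, `cohens_kappa`,
   `alert_coincidence_prob`, `roc_auc`, `bootstrap_ci`,
   `screening_curves`, `eval_report`, `extract_patient_features`,
   `embed_2d`, `render_map`).

## The network

The architecture is a small ResNet-style encoder: an initial 3x3
convolution (stride 1) with ReLU and BatchNorm, then four residual blocks.
Each block is one stride-2 3x3 convolution followed by three stride-1 3x3
convolutions, *every* convolution followed by ReLU then BatchNorm — the
conv → ReLU → BN order is kept exactly as specified even though BN-before-
activation is the more common ResNet idiom. A 1x1 stride-2 projection
convolution carries the shortcut across each block's downsampling, and the
block output is main path + shortcut. After the fourth block the spatial
map (input/16 on a side; 32 x 32 at the 512 px full scale) is collapsed by
global average pooling into the embedding (256-d at full scale), which a
single 256 x 2 linear layer maps to class logits and softmax
probabilities.

Channel widths are free configuration. The full-scale default
(stem 16, blocks 32/64/128/256) gives `count_parameters()` = 2,792,514
trainable parameters — the same order as the ~2.76M of the reference
design, whose exact width/bias/projection convention is not pinned down.
The desk-scale default used throughout the tests (`cnn_config_desk()`:
64 px input, stem 8, blocks 8/16/32/64, 64-d embedding) is the same
topology at 1/16 the compute.

Forward and backward passes are implemented in the package (im2col + GEMM
convolutions in compiled code, vectorised BatchNorm/ReLU/pooling in R);
gradient correctness is anchored by finite-difference tests.

### Focal loss

With `p_t` the predicted probability of the true class,

$$\mathrm{FL}(p_t) = -(1 - p_t)^{\gamma}\,\log(p_t),$$

averaged over the batch, with γ = 3 by default. At γ = 0 this is exactly
cross-entropy; larger γ down-weights well-classified examples so the
abundant easy negatives (16.5% prevalence in the motivating cohort, 8.4%
in the external one) do not dominate training. No α class weighting and no
oversampling are used: the focusing factor is the only imbalance
mechanism. Numerically, `p_t` is floored at 1e-7 before the logarithm, and
the gradient uses the same floor on `1 - p_t` so it stays finite at both
extremes.

### Optimiser and schedule

RAdam with β₁ = 0.9, β₂ = 0.999, ε = 1e-8 and the standard variance-
rectification rule (adaptive step only once the SMA length exceeds 5,
bias-corrected momentum SGD before that). The full-scale schedule
(`train_config_paper()`) is batch 32, 110 epochs, learning rate 0.001 for
epochs 1-80 and 0.0001 for 81-110. The desk schedule keeps batch 32 and the
same 8:2 high/low-rate proportion at 10 epochs (switch at epoch 8+1). Color
jitter in the desk schedule runs at roughly a quarter of the full-scale
ranges: the jitter magnitudes are free configuration, and a 10-epoch run
sees each image an order of magnitude fewer times than a 110-epoch run, so
it cannot average over strong photometric perturbations; the full-strength
ranges remain the `train_config_paper()` default.

## The synthetic cohort generator

No public H&E/PD-L1 TMA data ships with the package; instead
`generate_cohort` renders cohorts in which every downstream stage is
exercised and the best achievable performance is *known*.

Each patient draws a label at the configured prevalence and a latent
morphology scalar $z \sim N(0, 1)$ for negatives, $N(\mathrm{es}, 1)$ for
positives, where `es` is the `effect_size`. All label information reaches
the pixels only through $z$: rendered morphology parameters are
deterministic functions of $z$, so by the data-processing inequality the
pair-counting AUC of $z$ itself (`oracle_auc`, expectation
$\Phi(\mathrm{es}/\sqrt 2)$) upper-bounds the AUC of any model trained on
the images. This is the yardstick for the pipeline property tests: a
desk-scale model must recover most of — and can never exceed — the oracle.

Rendered morphology follows the qualitative contrast between
low- and high-scoring tumors: negatives get coherently oriented (streaming,
desmoplastic) stromal texture, moderate nucleus density and few
immune-cell dots; positives get crowded nuclei (tumor nests), many small
dark dots (tumor-associated immune cells) and weak stromal orientation.
Rate parameters use a log-linear link
$\mathrm{rate}(z) = \mathrm{rate}_{neg}\,e^{\beta z}$ with
$\beta = \log(\mathrm{rate}_{pos}/\mathrm{rate}_{neg})/\mathrm{es}$, so
the ratio of class means is exactly the configured ratio; orientation
coherence interpolates through a probit link. `effect_size = 0` collapses
the positive parameter set onto the negative one (no signal at all). The
renderer keeps ground-truth object lists (nuclei, dots) as attributes so
morphology claims are tested without a detector. Non-diagnostic annotation
categories are *rendered*, not just tagged: `No tissue` is a blank disc,
`Out of focus` a strong blur, `Deficient staining` a washed-out image,
`No TMA` a patient with no image; cohort-specific staining/digitisation
shifts are per-channel multiplicative factors applied before 8-bit
quantisation.

Units and defaults: nucleus densities are nuclei per 10⁴ px² of disc
(40 negative / 80 positive), immune dots are counts per image
(2 / 12), orientation coherence is in [0, 1] (0.7 / 0.2), lumen rings
average 1 per image. Default prevalence 0.165 and, for external-cohort
emulation, 0.084 with 1-4 images per patient, match the motivating
cohorts' tables; the default render size is 256 x 256 with a
2256 x 1440 full-frame mode.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: real H&E texture (no photorealism), nucleus
pleomorphism and clustering into genuine architectural patterns, scanner
noise beyond Gaussian/blur, batch effects beyond global channel scaling,
label noise from interobserver disagreement, and any real biological link
between morphology and PD-L1 expression. The synthetic results validate
the *machinery* (no leakage, honest aggregation, calibration that can only
help, statistics that match their definitions), not clinical performance.

## Study sizes used by the tests and the acceptance script

Chosen as desk-scale study conditions: training cohort of 200 patients at
prevalence 0.165 with 2-3 cores per patient rendered at 96 x 96
(≈500 images), 64 px network input, 10 epochs, 5-fold patient-level CV;
external shifted cohort of 150 patients at prevalence 0.084 with 1-4
images per patient and stain shift (0.85, 1, 1.12); `effect_size` 2.8
(expected oracle AUC 0.976, so the oracle stays above 0.95 with margin
against sampling noise at n = 200). Calibration uses 5 repeats averaged
per patient, over 10 seeds for the improvement property.

## Numerical and design choices

* **Tie at the operating threshold**: `score >= threshold` is high-PS; the
  rule is stated as below/above the threshold, and equality is assigned to
  the cautious side (stays in the reviewed group).
* **Threshold tuning**: among thresholds with CV sensitivity ≥ the floor,
  the one maximising the low-PS fraction; ties resolve to the lower
  threshold. The shipped untuned defaults are 0.5 (PD-L1) and 0.28 (PD-1).
  The accuracy column of the evaluation uses a separate accuracy-optimal
  threshold on training scores (`tune_threshold_accuracy`), since the
  triage threshold deliberately trades accuracy for NPV.
* **Split rounding**: floor for the test set, remainder to train
  (documented because the 860/2516 split pins the rule down); the split is
  unstratified by default with a `stratify` option, since stratification
  was left unstated.
* **Rotations** are restricted to multiples of 90° — "rotated" is
  otherwise underdetermined, and right-angle rotations are exact on the
  pixel grid.
* **Temperature jitter** is defined as opposite-sign multiplicative
  scaling of the red and blue channels (R × t, B / t).
* **Augmentation order** is fixed (geometric first, blur last); the order
  is otherwise unspecified.
* **BatchNorm**: ε = 1e-5, running-statistics momentum 0.1, biased batch
  variance; in eval mode the running statistics make inference exactly
  deterministic.
* **Bootstrap**: percentile intervals, B = 2000 by default, resampling at
  the patient level, seeded.
* **Calibration**: "last layer" means the linear head only; BatchNorm
  statistics are frozen with the backbone, which makes head fine-tuning on
  cached embeddings mathematically identical to fine-tuning the last layer
  of the network. Fine-tuning uses RAdam with focal γ = 3 at learning
  rate 1e-3 for 200 epochs — enough optimizer steps to train the small
  linear readout to convergence on the cached embeddings. (An
  under-trained head, e.g. a dozen epochs at 1e-4, barely moves from its
  initialisation and leaves calibration a no-op; head-only fine-tuning is
  cheap enough that convergence costs well under a second per repeat.)
  These hyperparameters are package defaults, not published values. The
  50/50 calibration split is stratified by label
  so both halves carry both classes whenever possible; a patient that
  never lands in a test half is reported `NA`, never silently dropped.
  The five repeats reuse one base checkpoint.
* **Full-set model seed**: the model trained on the entire training set
  after CV uses a fresh seed, not a fold's.
* **t-SNE** (`embed_2d`): exact O(n²) implementation — Gaussian input
  kernel with per-point bandwidths binary-searched to the target
  perplexity (default 30, capped at (n-1)/3), Student-t output kernel,
  gradient descent with momentum 0.5→0.8, early exaggeration 12 for 100
  iterations, adaptive gains, seeded random initialisation. Exact t-SNE is
  the right tool at cohort scale (hundreds of patients); no approximate
  neighbour structures are needed.
* **Degenerate inputs** are errors, not silent repairs: single-class AUC,
  empty cohorts, undersized crops, patients with conflicting annotations,
  calibration cohorts too small to hold both classes in both halves.

## Known limitations

The desk-scale CNN sees 64 px inputs; morphological detail that matters at
512 px (nuclear texture, membrane detail) is invisible, so desk AUCs
measure signal recovery on the synthetic contrast, nothing more. The
renderer's signal is dominated by cellularity/dot counts, which a small
CNN can read largely from low-order statistics; real H&E prediction is
far harder. Training reproducibility is exact here (single-threaded
deterministic kernels); on parallel BLAS the contract weakens to
statistical reproducibility of the loss trajectory while inference remains
exact. The `hecnn_cv` models are discarded after scoring to bound memory;
only histories and scores are kept.
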