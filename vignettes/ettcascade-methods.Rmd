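---
title: "Methods: cascaded localization of the endotracheal tube tip and carina"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cascaded localization of the endotracheal tube tip and carina}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The clinical problem

An endotracheal tube (ETT) that is placed too deep (toward the carina or a
mainstem bronchus) or too shallow is a common and dangerous finding in ICU
radiographs. The conventional quality target is a tip roughly 5 ± 2 cm above
the carina, so the clinically useful output is not a binary "tube present"
flag but the *distance in centimeters between the distal tube tip and the
carina*. `ettcascade` implements a serial three-stage convolutional pipeline
that reports exactly that:

1. **Stage 1 — coarse carina regression.** A CNN regresses the normalized
   `(y, x)` position of the carina on the full, square-padded, 512×512
   resampled radiograph.
2. **Stage 2 — hard-attention ETT classification.** A rectangular window
   with a 2:1 height-to-width ratio, spanning 50% × 25% of the model input
   and centered on the predicted carina, is cropped and a second CNN
   classifies ETT presence on the 256×128 crop.
3. **Stage 3 — refinement.** For ETT-positive exams a third CNN regresses
   four coordinates on the same crop: a refined carina and the distal ETT
   tip. The tip–carina distance is converted to centimeters with the exam's
   pixel spacing.

The cascade embodies two ideas: *iterative refinement* (the second look at
the carina happens at a higher effective resolution) and *hard attention*
(downstream networks only ever see the anatomically relevant window).

## Coordinate frames

All landmark bookkeeping runs through four named frames — `ORIGINAL`
(native detector grid), `PADDED` (square zero-padded canvas), `MODEL`
(resampled network input) and `CROP` (attention window grid) — connected by
invertible per-axis affine maps (`y' = y·s + o`). Coordinates are 0-based
`(row, col)` pairs at pixel centers. Zero padding is applied to the
right/bottom by default, which makes `ORIGINAL` and `PADDED` coordinates
coincide; symmetric padding is available as an option. Physical distances
apply the per-axis mm/px spacing *before* the Euclidean norm, so anisotropic
detectors are handled correctly.

One deliberate geometric choice: the stage-2/3 crop is *defined* in the
`MODEL` frame (fractions of the 512×512 input) but *extracted* from the
padded original-resolution image over the same physical window. At 512×512
inputs the two are pixel-identical; for smaller model grids the crop keeps
the native resolution — which is the point of hard attention: each crop
pixel is physically smaller than a model pixel.

## Backbone

All three networks share one backbone: a stack of *conv blocks* (3×3
convolution → batch normalization → LeakyReLU, negative slope 0.3), arranged
in resolution levels. Every level after the first is entered through a
stride-2 convolution that performs the subsampling and carries the channel
increase; stride-2 blocks count toward the block total. The full-scale
default is 8 levels with blocks `[5, 4, 4, 4, 4, 3, 3, 3]` (30 blocks, 7
subsamplings) and channels `[48, 56, 64, 76, 88, 100, 114, 128]`: capacity
is deliberately front-loaded, since the carina and a 3–5 px tube line are
small, high-frequency structures that must be resolved before subsampling.
The block distribution beyond the first two levels and the intermediate
channel counts are this package's choice (the printed constraints are the
totals, the 5/4 front splits and the 48→128 range); both are configurable.

Heads: classification uses global average pooling followed by a linear
layer and softmax cross-entropy; coordinate regression uses a **linear
readout over a coarsely average-pooled (≤4×4) final feature map**, trained
with MSE against coordinates normalized to `[0, 1]`. Two regression-head
decisions deserve justification:

* *No global average pooling for regression.* GAP is (up to padding
  effects) translation-invariant, which makes absolute-coordinate
  regression structurally near-unlearnable. Pooling to a coarse 4×4 grid
  and flattening keeps the readout linear while preserving the spatial
  layout.
* *Near-zero initialization of the final linear layer* (Xavier scaled by
  0.01). With a full-scale random readout the network's output inherits the
  variance of several hundred noisy features, and the short fixed training
  schedule (see below) spends most of its updates shrinking that noise
  floor instead of learning. Starting the readout near zero removes the
  floor; all other layers keep plain Xavier-uniform initialization.

Everything is implemented in a compact Rcpp/Armadillo engine (im2col + GEMM
convolutions, exact analytic gradients, Adam); gradients are verified
against finite differences in the test suite.

## Preprocessing and augmentation

Inputs are zero-padded to square, bilinearly resampled to 512×512 (the
model grid), and z-scored per image. A constant image falls back to
`sd = 1` with a warning. Resampling positions are clamped at the far canvas
edge so the sub-pixel overshoot of the `dst/src` grid convention does not
bleed zero into the border.

Training-time augmentation has two independent parts:

* **Normalization jitter**: the stored z-score statistics `(μ, σ)` are
  multiplied by a factor uniform in `[0.90, 1.10]` and the image is
  re-normalized with the jittered statistics.
* **Geometric translation + scale**: per-axis integer translations uniform
  in `[-14, +14]` px and a scale factor uniform in `[1 ± 14/(side/2)]`
  about the image center. The displacement budget of 0–14 pixels is read as
  a bound on the *total* corner displacement: a candidate transform is
  rejection-resampled until the largest Euclidean displacement of the four
  image corners is ≤ 14 px. Landmarks receive exactly the same forward
  transform; consistency is property-tested by tracking the intensity
  centroid of a rendered dot through the warp.

Augmentation is applied on the model grid (after resampling), which keeps
the 14-px bound scale-consistent across input sizes; this is configurable.

## Training and cross-validation

Each stage trains with Adam (learning rate 5e-4, batch size 12) for 3
epochs, after which the learning rate is divided by 10 for one fine-tuning
epoch — 4 epochs total, no early stopping. Stage-2/3 training crops are
centered on the ground-truth carina plus Gaussian jitter (σ = 8 model px)
to emulate stage-1 error; at evaluation time crops are centered on the
stage-1 prediction, matching deployment. Stage 3 trains only on
ETT-positive exams with coordinate targets (mirroring a cohort where only a
subset carries landmark annotations).

Cross-validation is five-fold and *patient-grouped*: patients are shuffled
and dealt round-robin, every exam follows its patient, and the harness
asserts (not assumes) that no test patient's exams appear in training.

## Evaluation

Localization errors are reported as mean/median/25th/75th-percentile
absolute distances in centimeters (linear-interpolation quantiles, R type
7; the quantile convention is unstated upstream and is documented rather
than claimed). Classification reports accuracy, sensitivity, specificity,
PPV, NPV with **Wilson score** 95% intervals, and AUROC via the
Mann–Whitney rank statistic (ties count ½, verified against a brute-force
all-pairs oracle) with a seeded stratified percentile bootstrap (2000
resamples) for its interval. The upstream CI methods are unstated; these
choices are documented, not claimed equivalent.

## Report parsing

Cohort labeling uses case-insensitive regular-expression families for
"endotracheal tube" / "ET tube" / "ETT" with a 5-token negation window
(`no`, `removed`, `extubated`, …) that never crosses a sentence boundary;
conflicting sentence-level votes yield `UNCERTAIN`, which cohort building
excludes. Reference distances are parsed from `<number> <cm|mm> above/from
the carina` phrases, mm converted to cm, bounded to a plausible (0, 15] cm.
The exact patterns are this package's contract (fixed by a 40+-sentence
fixture suite), not a reconstruction of the original study's parser.

## The synthetic cohort

Real credentialed radiographs cannot ship with a package, so every stage is
exercised on a synthetic generator whose *stated world* mirrors the study
population:

* ~50% ETT prevalence, assigned at patient level; repeat exams share the
  patient's anatomy up to a small translation.
* Tip–carina distances drawn from a lognormal with median 4.10 cm and
  log-sd 0.3807, truncated to [0.5, 9] cm. This reproduces the reported
  median and approximates the quartiles (≈3.2/5.3 cm vs 3.00/5.30) and mean
  (≈4.41 vs 4.29); a two-parameter family cannot match all four summary
  statistics, and the median/quartile fit was preferred.
* Pixel spacing uniform in 0.6–0.8 mm/px *at a 512-px reference grid*,
  rescaled by `512/image_h` for other sizes, so a smaller matrix images the
  same physical chest at coarser resolution. A fixed mm/px independent of
  matrix size would shrink the field of view and push much of the distance
  distribution outside both the image and the crop window — physically, a
  256-px chest radiograph has ~1.3 mm pixels, not 0.7 mm.
* Anatomy: carina uniform in the central region (rows 45–65%, columns
  45–55%), a slightly curved dark trachea band (8–14 px wide at 512) from
  the top margin, two bronchial branches at 25–40°, a bright 3–5 px ETT
  line terminating at the tip, optional off-axis distractor tube (30%),
  low-frequency background blobs and Gaussian noise. Report sentences are
  generated from the same geometry, so the NLP, geometry and rendering
  modules can be cross-validated against each other.

What a green synthetic run establishes: that the pipeline's plumbing,
losses, geometry and optimization recover known parameters end-to-end on
images with the stated population statistics. What it does not establish:
performance on real radiographs — no rib shadows, no rotated or
under-penetrated films, no overlapping support devices beyond one
distractor line, no pathology. The printed clinical metrics of the original
cohort are out of desk-scale reach by design.

## Numerical and degenerate-input policy

* Bilinear interpolation everywhere (nearest-neighbor available for masks);
  out-of-window regions zero-filled at crop extraction.
* Regression outputs are raw linear logits; stage-1 outputs are clamped
  into frame bounds instead of erroring.
* Decision threshold 0.5, configurable; ETT-negative exams keep the coarse
  carina as final (stage 3 is gated), configurable to always refine.
* Missing pixel spacing gates all centimeter outputs behind an explicit
  pixel-units opt-in.
* Seeds flow explicitly: weight init, shuffling, augmentation, fold
  assignment, bootstrap and the generator all accept seeds, and identical
  seeds give bit-identical results on a fixed build.

## Known limitations

The acceptance suite trains the full cascade at desk scale (1,000 synthetic
training exams at 256 px, the fixed 4-epoch schedule, ~1.3 mm pixels) and
asserts four parameter-recovery outcomes. Three hold comfortably (coarse
carina error, refinement strictly improving on the coarse estimate,
near-perfect presence classification). The fourth — a 0.5 cm median error
on the recovered tip–carina distance — is not reached at this scale: 0.5 cm
is under 4 pixels here and stage 3 sees only ~500 positive exams (168
optimizer updates under the fixed schedule). The assertion is kept as-is
and fails honestly rather than being loosened; head-style, capacity,
augmentation and target-parameterization variants were explored and
documented before accepting the shortfall.

Single-tube assumption (no NG-vs-ETT disambiguation beyond the distractor),
frontal views only, no lateral triage, no pretrained encoders or heatmap
heads, CPU-oriented engine (no GPU path), and a 16-bit PGM + JSON sidecar
interchange format for synthetic exams (no PNG codec is available in the
target stack; DICOM reading is limited to uncompressed explicit-VR little
endian).
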