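---
title: "Detecting aggressive and indolent prostate cancer on bi-parametric MRI with spcnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting aggressive and indolent prostate cancer on bi-parametric MRI with spcnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Prostate MRI (T2-weighted plus the apparent diffusion coefficient map,
"bi-parametric" MRI) is read by radiologists to locate cancer before targeted
biopsy. Two failure modes matter clinically: lesions that are invisible or
hardly visible on MRI are missed, and radiologist outlines systematically
underestimate the true histological extent of a lesion. spcnet implements a
per-pixel detector that classifies every in-gland voxel as **normal tissue**,
**indolent cancer** (Gleason pattern 3) or **aggressive cancer** (Gleason
pattern 4/5), trained against histopathology-derived labels rather than
radiologist outlines, together with the complete evaluation protocol
(pixel-, lesion- and patient-level) and a radiologist-comparison mode.

Because suitable clinical data are not publicly deposited, the package ships
a first-class synthetic phantom generator that emulates the statistical
structure of a prostatectomy cohort. Every stage of the pipeline is
developed and tested against these phantoms.

## Ground-truth construction

Two label sources are fused per voxel into a 3-class soft label
$(y_1, y_2, y_3)$ = (normal, indolent, aggressive):

* a Gleason-pattern map (patterns 3, 4, 5), which **overrides** everything:
  pattern 4/5 gives $(0,0,1)$, pattern 3 gives $(0,1,0)$;
* a pathologist cancer outline: voxels marked cancer but lacking grade
  information get the maximally uncertain cancer label $(0, 0.5, 0.5)$ and
  are tracked by an `ungraded` flag;
* everything else is normal, $(1,0,0)$.

Cancer labels falling outside the prostate segmentation are forced to normal
with a warning rather than an error: histopathology-to-MRI registration is
known to carry a 2-3 mm alignment error, so stray voxels are expected in
real data. The `ungraded` flag matters twice downstream: those voxels
contribute fractional mass (0.5/0.5) to the training loss and the class
weights, but they are excluded from both sides of the pixel-level indolent
and aggressive evaluations, and they never count toward a lesion's
aggressive-voxel numerator.

## Preprocessing

The chain is: in-plane resampling to a common spacing (bilinear for
intensities, nearest-neighbour for masks and label maps; slice spacing is
never resampled), a square in-plane crop centred on the prostate-mask
centroid (ties round toward the smaller index, out-of-grid regions are
zero-padded), histogram-landmark intensity standardization, and in-gland
z-scoring.

Standardization deserves detail because the method is named but not fully
specified by its usual description. Per sequence (T2w, ADC independently):

1. each training volume's in-gland intensities are linearly rescaled so its
   1st/99th percentiles land on 0/100 (the *anchored rescale*; this makes
   volumes from different scanners commensurable before averaging);
2. the landmark percentiles (deciles 10..90 by default) are computed in that
   space and averaged across training volumes;
3. at application time a volume's own (rescaled) percentiles are mapped onto
   the mean landmarks by a monotone piecewise-linear function, applied to
   prostate voxels only, with end-segment slopes extended beyond the
   outermost landmarks.

Whether the original method rescales before averaging is not specified
anywhere we could verify; the anchored rescale is this package's choice and
is isolated in one internal function should a different anchoring be
preferred. Landmarks are learned **once on the training split** and written
to a YAML artifact that is applied frozen to every test case — the pipeline
enforces this train/test asymmetry structurally.

## The network

The model is a 2.5D, two-branch, multi-scale fully convolutional network in
the holistically-nested (HED) family. Three adjacent slices of each sequence
enter as input channels (the "2.5D" convention: volumetric context without
3D convolution), one branch per sequence. Each scale is a block of two 3x3
convolutions + ReLU followed by 2x2 max-pooling; after `branch_depth` scales
the two branches are concatenated and the remaining scales are shared. Every
scale emits a 3-class 1x1 side output, upsampled to the input size by fixed
bilinear interpolation; the fused head is a 1x1 projection of the
concatenated upsampled side outputs, initialized as their average. Softmax
is applied at every output. With the default 5 scales and branch depth 2
there are 7 side outputs (2 sequences x 2 branch scales + 3 shared scales).

Internals that the architecture diagram of the HED family leaves open —
filter widths, kernel size, activation, pooling and the use of deep
supervision — follow the VGG/HED idiom (3x3 kernels, ReLU, max-pool,
channel doubling per scale with a cap, deep supervision on) and are all
exposed in `model_config()`. They are declared approximations, not claims of
fidelity to any particular diagram.

There is no deep-learning framework dependency: the package includes a
compact CPU engine (im2col + BLAS gemm convolutions; the input gradient is
computed as a full convolution with rotated transposed weights; fixed
bilinear resizing as a separable linear operator and its adjoint). Backprop
is verified against central finite differences in the test suite at a point
where no probability is clipped; away from such points ReLU kinks make
finite differences disagree by design, not by defect.

## Training

The loss is class-weighted categorical cross-entropy
$-\frac{1}{N}\sum_n \sum_{i=1}^3 w_i\, y_i^{(n)} \ln \hat y_i^{(n)}$, with
$w_i = M / \sum_m y_i^{(m)}$ the inverse class frequency over the training
scope ($M$ = number of in-scope pixels; soft labels contribute fractional
mass). These weights make every class's expected weighted contribution equal
— the property, not the formula, is what the tests pin. Predictions are
clipped to $(10^{-7}, 1-10^{-7})$ inside the log only.

Choices where the protocol is silent, and our resolutions:

* **Loss scope** (`loss_mask`): default `prostate_only` — the sum runs over
  in-gland pixels of the selected slices, consistent with gland-restricted
  normalization and evaluation; `full_frame` is available.
* **Slice selection**: cancer cases contribute only slices containing
  cancer (each coupled with its 2.5D neighbours); normal cases contribute
  every slice intersecting the prostate. The normal-case rule is our
  decision; the alternative (a subset) is not stated anywhere.
* **Deep supervision**: the loss is applied to every side output plus the
  fused head with uniform weights (mean over heads), configurable off.
* **Ungraded pixels** train with their 0.5/0.5 mass and enter the
  class-weight denominators.

Optimization is Adam (beta 0.9/0.999, learning rate 1e-3, no schedule, no
weight decay, no early stopping), 25 epochs at batch size 32 in the
full-scale configuration. Augmentation applies one shared geometric
transform per sample — rotation uniform in (-15, 15) degrees and a fair
left-right flip — bilinear for images, nearest-neighbour for labels and
mask, background fill outside the frame. Cross-validation is patient-level:
a seeded shuffle partitioned by largest remainder, each fold model trained
on the complement, and the prediction-time model is the arithmetic mean of
the fold models' fused softmax maps.

## Lesion-level machinery

Ground-truth lesion outlines are built from the fused cancer labels by 3D
morphological closing (ellipsoidal element, default radii 3 mm in-plane and
3 mm through-plane — one slice at typical spacing; the element size is not
specified by the protocol and is config-exposed) followed by 26-connected
component extraction and a 250 mm3 volume filter. The filter applies to
evaluation only; training labels never pass through this module. A lesion is
*detected* when the 90th percentile of the model probabilities inside its
outline exceeds the threshold — percentile convention pinned to linear
interpolation between order statistics (R type 7), and "exceeds" pinned to
strict `>` (configurable to `>=`), because small lesions can flip on either
convention.

Negatives for the lesion-level ROC are prostate sextants: the gland is split
at the left-right bounding-box midline (boundary column to the left) and
into three contiguous largest-remainder slice tertiles (apex/mid/base).
Sextants with at least 95% normal-argmax voxels (inclusive boundary) are
negatives, scored by the same 90th-percentile statistic over the whole
gland's sextant voxels (whether negatives should be restricted to evaluated
slices is unstated; we use the whole gland).

Per-patient: a patient with clinically significant (CS) lesions is a true
positive if *at least one* CS lesion is detected; normal patients are false
positives if the thresholded + morphologically processed aggressive channel
contains any predicted lesion. CS is defined per lesion as >= 1% (or >= 5%)
aggressive voxels.

The radiologist comparison treats an outline as a prediction with
probability 1.00 of aggressive cancer inside and evaluates it identically;
the combined model **adds** the two probability volumes — the sum (range
[0, 2]) is a score, not a probability, and is flagged as such. The detection
rule is applied to the summed channel with the same threshold, faithful to
"adding" the predictions (a logical OR of detections is the alternative
reading; addition dominates both components' scores, so combined sensitivity
can only rise).

Detection thresholds are calibrated once on pooled validation-fold pixels by
maximizing Youden's J per class (the selection procedure behind "empirical
testing" is not specified; Youden is our choice), then frozen to a YAML
artifact before any test-set evaluation. The chosen threshold is the
midpoint between adjacent unique scores, so it is invariant to pool
reordering.

## The phantom generator

The generator emulates, per case: a smoothed, randomly perturbed ellipsoidal
gland (~40 x 30 x 38 mm, 20-80 cm3) on a 0.29 mm / 3 mm grid; 1-2 lesions
per cancer case with lognormal volumes (mu = 7.04, sigma = 0.96 in mm3,
mean ~1.8 cm3, long tail, draws rejected outside [50, 20000] mm3 and
degenerate fragments below 50 mm3 erased); lesions as Gaussian-smoothed
thresholded blobs grown to their target volume inside the gland, pattern 3
throughout with an embedded pattern 4/5 core in mixed lesions (so aggressive
voxels are a strict subset); T2w/ADC intensities as tissue base + class
offsets + smooth multiplicative bias field (+-5%) + Gaussian noise, with
aggressive voxels receiving the largest ADC decrease; an optional 1-voxel
ungraded pathologist rim per lesion (probability 0.3) to exercise the
0.5/0.5 label path; and radiologist outlines that drop each lesion with
probability 0.3 and erode survivors in-plane to ~70% of their volume,
mimicking underestimation of lesion extent.

Default contrasts (T2w: -60/-100; ADC: -350/-700 for indolent/aggressive
against bases 400/1400, noise 6% of base) make lesions conspicuous on ADC
and subtle on T2w — the qualitative appearance of the disease — but they are
free parameters: no per-class lesion-contrast statistics exist to calibrate
against, so separability on phantoms is by construction *easier* than on
clinical data. Passing phantom tests therefore demonstrates that the
pipeline's machinery is correct end to end, **not** that clinical-cohort
AUCs would be reproduced. The phantoms also omit zonal anatomy
(peripheral/transition signal differences), DCE dynamics and scanner
artifacts, all declared out of scope.

All randomness descends from one seed through named substreams (cohort,
per-case mask/lesions/rendering, fold assignment, per-epoch shuffling and
augmentation, weight init), making cohorts bit-identical and training runs
reproducible under a fixed seed.

## The scaled-down experiment

The self-contained experiment (`run_phantom_experiment()`, also behind
`scripts/acceptance.R`) uses problem sizes chosen to run on one CPU core in
a few minutes: 20 training + 12 test phantoms at the default class mix,
geometric preprocessing to 0.6 mm / 96 px (a 96 px crop at the native
0.29 mm would truncate the gland, so the scaled-down geometry trades
resolution for field of view), a 5-scale network with base width 8, and
2-fold cross-validation for 5 epochs. At this cohort size the full-scale
batch geometry would allow only ~75 optimizer updates per fold, so the
scaled-down configuration uses batch size 2; epochs, folds, cohort size and
the generator's contrast/noise defaults are part of the stated conditions
and are not adjusted. Thresholds come from the pooled validation folds;
evaluation runs on the held-out cohort only.

```r
library(spcnet)
res <- run_phantom_experiment(pipeline_config(seed = 1), verbose = TRUE)
res$evaluation$pixel      # per-class pixel AUC / Se / Sp
res$evaluation$lesion_all # all-cancer lesion-level ROC
res$evaluation$patient    # per-patient Se / Sp
```

## Numerical choices and degenerate inputs

* Percentiles everywhere are quantile type 7 (linear interpolation).
* Argmax ties break toward the earlier class (normal > indolent >
  aggressive); ungraded 0.5/0.5 voxels are therefore never "normal".
* Masks resample by nearest-neighbour and must stay in {0, 1}; label maps
  keep their 4-symbol alphabet.
* Degenerate inputs error early with named messages: empty prostate masks,
  constant in-gland histograms, non-increasing landmarks, a class with zero
  training mass, glands spanning fewer than 3 slices, fewer cases than
  folds, single-class threshold pools. Zero lesions is a valid phantom
  outcome, not an error.
* Morphological closing pads internally so results never clip at the grid
  boundary, guaranteeing closing ⊇ input and idempotence.
* Training aborts with a named diagnostic on non-finite loss.

## Known limitations

* The network engine is CPU-only and sized for the scaled-down experiment;
  full-scale (224 px, width 16, 25 epochs, fivefold) training is expressible
  but slow in this implementation.
* Phantom separability exceeds clinical reality (see above); absolute
  metric values on phantoms say nothing quantitative about patient data.
* T2w-ADC co-registration is assumed done: inputs must share a voxel grid,
  and mismatches are rejected rather than corrected.
* Left/right sextant splitting uses the gland bounding box, not the patient
  midline (the protocol does not say which); the difference only matters
  for markedly asymmetric glands.
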