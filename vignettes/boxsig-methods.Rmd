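---
title: "Box-derived radiomics signatures: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Box-derived radiomics signatures: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`boxsig` studies whether a radiomics signature extracted from a lesion
*detection bounding box* can stand in for one extracted from a manual
segmentation when classifying benign versus malignant breast lesions in
B-mode ultrasound. This vignette is the package's account of the science:
the models, the tunable parameters and their defaults, the numerical
conventions, and the places where a genuinely open design question was
settled one way rather than another.

## The speckle phantom model

No clinical images ship with the package; every stage is exercised on
synthetic phantoms whose ground truth is known by construction.

A phantom is built in four steps:

1. **Echogenicity map.** A constant background (mean 110 gray levels)
   with one lesion whose interior is offset by `echo_contrast` (default
   +20 for benign — iso/hyperechoic — and −40 for malignant —
   hypoechoic). Within-lesion echotexture is smoothed Gaussian noise
   rescaled to `heterogeneity_sd` (5 / 20 gray levels).
2. **Margin.** The lesion boundary is a radially perturbed ellipse,
   `r(θ) = r0(θ) · (1 + A sin(kθ + φ))` with lobe count `k` drawn from
   5..9. Benign lesions are smooth (`A = 0`); malignant ones are
   spiculated (`A = 0.25` by default).
3. **Speckle.** The map is multiplied by a unit-mean Rayleigh field —
   the canonical first-order model of fully developed ultrasound
   speckle — blended by `speckle_scale` (1 = full speckle) and smoothed
   with a σ = 1.5 px Gaussian to mimic the lateral point-spread of a
   B-mode system.
4. **Quantization.** Min-max rescale to `[0, 255]` and rounding to
   8-bit. The degenerate-range convention (a constant image maps to 0)
   is used everywhere in the package.

Every phantom is a pure function of its parameter list: identical
parameters give bit-identical pixels, masks and boxes. Per-phantom seeds
in a cohort are derived deterministically from the master seed.

Three **simulated annotators** perturb the center and size of the tight
ground-truth box with zero-mean Gaussian noise of sd `jitter_sd = 0.02`
in normalized coordinates (so severity is frame-size invariant). No
inter-observer variability figures were available to calibrate this; 2%
of the frame is a modeling choice meant to represent careful readers,
and at that level the jittered boxes keep IoU > 0.5 with the truth in
over 99% of draws (verified by Monte Carlo in the test suite).

**What the phantoms do not capture.** There is no wave propagation, no
transducer geometry, no attenuation, no posterior shadowing or
enhancement (an optional additive gradient exists but is off by
default), and only one lesion per frame. Most importantly, the two
classes differ in *four* strong, independent cues (contrast sign,
heterogeneity, spiculation, and their interactions), which makes them
far more separable than clinical cases. Passing classification tests on
phantoms therefore demonstrates that the pipeline is wired correctly
and that box masks carry the class signal — not that any particular
clinical accuracy would be attained.

## Preparation and augmentation

`normalize_crop()` center-crops to 600 × 700 and then min-max normalizes
to 8-bit (cropping first so the output always spans the full range; the
order is a documented convention). `despeckle_dwt()` performs one
level of an orthogonal, periodized 2D wavelet transform, soft-thresholds
the three detail subbands at the universal threshold
`σ̂ sqrt(2 log n)` with `σ̂ = MAD(HH)/0.6745`, and inverts. The
wavelet filter banks (Haar, two coiflets) are implemented natively as
orthogonal analysis matrices; perfect reconstruction is tested to
1e−9.

The ten augmentation scenarios produce exactly 3, 6, 96, 4, 4, 1, 1, 1,
1 and 1 images. Two factorizations deserve a note, because only the
output counts — not the construction — are fixed by the study design:

* Rotations: 6 = {45°, 90°, 135°} × {clockwise, counter-clockwise},
  resampled back to the original frame.
* Shears: 96 = 4 base orientations (original + 3 flips) × 6 angles
  (5°..30°) × 2 shear axes × 2 signs — the only factorization consistent
  with the printed count.

Geometric scenarios warp the ground-truth mask through the *same* map as
the pixels (nearest-neighbor for the mask, bilinear for the image) and
return the axis-aligned hull of the warped mask; vacated image pixels
are filled by symmetric reflection, while the mask is zero-filled so
reflection can never create spurious lesion copies. Translations move by
exactly 10% of each dimension in the four diagonal directions. Filter
derivatives (EXP, LN, SQUARED, SQRT) apply their nonlinearity to
intensities rescaled to `[0, 1]` and min-max map the result back to
8-bit — the source material never states intensity ranges, so one common
display range is used and documented. The eight dataset assemblies sum
their scenarios' counts: 118 per input image for the everything
assembly, 109 for spatial-only.

## The detector

The trainable branch is a sliding-window cascade in the classical
mold: HOG descriptors (unsigned orientation histograms per cell, L2
block normalization) feed stages of discrete-AdaBoost decision stumps;
each stage's threshold passes ≥ 99% of training positives, and stage
`k` trains against the negatives surviving stages `1..k−1`, refilled by
hard-negative mining. Three implementation decisions matter:

* **Pre-smoothing** (`smooth_sigma = 3`). Block-normalized HOG equalizes
  gradient energy, so on raw full-strength speckle the descriptor is
  dominated by noise orientation, which is uniform — the lesion signal
  all but vanishes. Smoothing before the gradient computation (the same
  despeckling idea applied ahead of feature extraction) restores the
  boundary signal. The same smoothing is applied at training and
  detection.
* **Representation consistency.** Training windows are harvested from
  the same multi-scale sliding grids used at detection time: positives
  are the grid windows best overlapping the ground truth (plus jittered
  ones), negatives are far windows (IoU < 0.1) from the same grids.
  Training on resized ground-truth crops instead introduces a systematic
  train/test descriptor mismatch that we measured to destroy
  generalization.
* **Box voting.** After NMS each kept detection is replaced by the
  score-weighted mean of all surviving windows overlapping it and
  rescored by its cluster mass. A true lesion attracts many windows
  across positions and scales; an isolated speckle fluke does not, and
  the averaged box is finer-grained than the stride/scale grid.

The detector is validated on *high-contrast* phantoms (echo contrast
−70, half-strength speckle), where the top detection exceeds IoU 0.5 on
well over 70% of a held-out 30-image cohort. On default full-speckle
phantoms recall is substantially lower and strongly seed-dependent — an
honest reflection of what a desk-scale HOG cascade can do against heavy
speckle, and one reason the pipeline treats the detector as pluggable:
`load_external_detections()` accepts any detector's output (CSV or
VOC-style XML) so the downstream comparison is detector-agnostic. GPU
detectors with pretrained weights are deliberately out of scope.

The VOC XML dialect written and read by the package stores the 0-based
left/top corner and the exclusive right/bottom corner, so `w = xmax −
xmin`; files round-trip exactly and the convention is fixed rather than
auto-detected.

## The joint IoU / LE evaluation rule

IoU is overlap over union. LE is the Euclidean composite of center
offset and size mismatch. The defining equation mixes pixel and
percentage glosses that cannot hold simultaneously on a non-square
frame, so the package adopts the only self-consistent reading: all four
terms are computed on box coordinates divided by the matching image
dimension. LE is then dimensionless, scale-free (doubling frame and
boxes together leaves it unchanged — a tested invariant), and the 0.1
threshold applies to any frame.

The outcome rule: a missing detection is a false negative; a detection
is a true positive when `IoU > 0.5`, **or** when `LE < 0.1` *and* IoU is
at least `iou_floor`; otherwise a false positive. The rescue clause
covers detections that are well-placed and well-sized but, e.g.,
slightly inset (IoU 0.48, LE 0.01 → TP); the floor exists because a box
of similar size and position with essentially no overlap (IoU 0, LE
0.07) must remain a false positive. The reference decisions bound the
floor within (0, 0.48]; the default is 0.25 and it is configurable,
since the exact value used in the original analysis is not recoverable.
Setting `le_tp = 0, iou_floor = 1` recovers pure-IoU scoring and
`iou_tp = 1, iou_floor = 0` pure-LE scoring (tested degenerations).
Per-image scores are the arithmetic means across annotators; outcomes
are assigned per annotator and pooled (the alternative — thresholding
the per-image mean — is a switch away, as the protocol is ambiguous on
this point). Dataset summaries use the sample standard deviation
(n − 1); with one image the sd is reported as 0 and flagged. When no
false negatives occur, recall falls back to `TP / N` with `N` the total
ground-truth count. No true-negative bookkeeping exists for detection.

## Radiomics

Features are extracted per image type × feature class, re-discretizing
the filtered image inside the mask each time with the fixed bin width of
25 gray levels (`level = floor((I − min_ROI)/25) + 1`). The six classes
have fixed sets — first order 18, GLCM 24, GLRLM 16, GLSZM 16, GLDM 14,
NGTDM 5, i.e. 93 per image type — following the standard 2D radiomics
conventions: symmetric GLCMs at distance 1 averaged over the four 2D
directions (features computed per direction, then averaged), run-length
matrices over the same four directions, size zones by 8-connectivity,
dependence matrices with distance 1 and equality tolerance 0 (the
center pixel counted, so dependence ≥ 1), and a 1-neighborhood NGTDM.
Out-of-mask neighbors are excluded everywhere. Every feature has a
defined finite limit on a single-level region (entropy 0, uniformity 1,
correlation 1, and so on) — never NaN. All matrix builders are verified
against exhaustive pair/run/zone/dependence enumeration on random
discretized ROIs.

The default image-type stack has 11 entries: original, five pointwise
derivatives (squared, square root, logarithm, exponential — same
`[0,1]`-rescale convention as augmentation), Laplacian-of-Gaussian
(σ = 3 px), Sobel gradient magnitude, uniform rotation-invariant LBP
(radius 1, 8 neighbors), and the LH/HL/HH detail subbands of a
single-level *stationary* coif1 transform (undecimated, so subbands
stay pixel-aligned with the mask). 11 × 93 = 1023 features. Twelve
types would be the natural reading of the filter list (four wavelet
subbands), but only eleven reconcile with the published feature total;
the approximation (LL) subband — the one closest to a brightness copy
of the original — is the one omitted, and the set is configurable.
Filters are applied to the full frame before masking, so tissue context
adjacent to the ROI enters the filtered values: that is precisely the
information a box segment adds relative to a tight contour, and the
premise of the comparison. Shape features are deliberately absent — a
signature that needs the lesion contour could never be derived from a
box.

Normalization is z-scoring with statistics estimated on the
feature-selection subset and reused unchanged on the classification
subsets; zero-variance features map to 0 and are flagged.

## Signature selection

The response is binary, so the LASSO is the binomial one: L1-penalized
logistic regression (glmnet; no internal re-standardization, intercept
unpenalized) along 100 log-spaced penalties from the analytic
`λ_max = max_j |x_j'(y − ȳ)|/n` down to `λ_max · 10⁻⁴`. The penalty is
chosen by stratified, seeded 10-fold cross-validation of the binomial
deviance under the *minimum* rule — the 1-SE rule would shrink the
signatures far below the dozens of features the study design calls for.
The signature is the nonzero-coefficient set ordered by absolute
coefficient. One subtlety: the exact LASSO path lets variables leave the
active set transiently as the penalty falls, so support size is monotone
only as a trend; the tests assert small dips and a high rank
correlation rather than literal monotonicity, which the true solution
path does not obey.

On the calibration design used throughout (n = 200, p = 100, five
informative coefficients of 2.0), cross-validated selection recovers at
least four of the five planted features in ≥ 90% of 20 seeded
replicates, the null model appears at and above `λ_max`, and the
unpenalized end of the path agrees with `glm()` to better than 1e−4.

## Classification and AUC comparison

Three KNN presets mirror the classifier families of interest:
*weighted* (k = 10, inverse-squared-distance weights, Euclidean),
*uniform* (k = 10 — the "medium-k" preset; the per-neighbor mean of
labels), and a *random-subspace ensemble* (30 learners, subspace
dimension ⌈p/2⌉, 1-NN base learners, seeded subspace draws). The
ensemble aggregates per-learner scores by averaging, so a one-learner
full-space ensemble is exactly the uniform variant — a tested
degeneration that also keeps the score a proper malignancy probability
for ROC purposes. Validation schemes are restricted to the study's set:
stratified 5- or 10-fold CV, or 20/25/30% stratified holdout, all
seeded. Confusion metrics are the standard sensitivity `TP/(TP+FN)`,
specificity `TN/(TN+FP)` and accuracy, in percent, at a 0.5 score
threshold; undefined ratios are reported as NA rather than invented.

AUROC is computed as the midrank statistic — exactly the trapezoid area
of the threshold-swept ROC and exactly `P(score⁺ > score⁻) +
½P(tie)`; the equality with an O(n²) pairwise oracle is asserted to
1e−12. DeLong's test uses the placement-value (structural component)
formulation with the paired covariance of the two score vectors and a
two-sided normal p-value; identical scores give z = 0, p = 1 by
construction, swapping the arguments flips the sign of z, and on a
synthetic pair the p-value agrees with a 5,000-replicate stratified
bootstrap within 0.02.

`compare_mask_sources()` wires the design together: one feature table
per mask source on identical samples, a per-source signature and
classifier, one common stratified test split, and DeLong comparisons of
every source against the manual-segmentation reference.

## The end-to-end study and problem sizes

`run_experiment()` executes the whole design with strict data-pool
separation: a detection pool (train/validation/test split in roughly
25/37.5/37.5% proportions) and a classification pool split into a
feature-selection subset (50%) and classification train/test subsets
(28.5/21.5%) — proportions chosen to mirror the role structure of the
original cohorts at synthetic scale. The feature-selection subset and
the classification test split are disjoint by construction and this is
asserted at run time. Every artifact records the hash of the scientific
configuration (the artifact directory is excluded from the hash so
reruns into different directories are recognized as the same
experiment), and a rerun with an identical configuration reproduces
byte-identical CSV/JSON artifacts.

Default problem sizes are deliberately desk-scale: 20 + 20 phantoms in
the detection pool, 70 + 70 in the classification pool, 280 × 320
frames, and a four-type radiomics stack (original, LoG, gradient,
wavelet-HH) for the study loop — the full 11-type stack remains the
extraction default and one full-size extraction is exercised in the
acceptance checks. The default box source is a simulated external
detector (ground-truth boxes jittered by 2% and read back through the
detections adapter, so the file pathway is exercised); switching
`box_source = "detector"` routes the trained cascade's boxes into the
comparison instead.

On this design the box-derived and manual-mask classifiers are
statistically indistinguishable — the five-seed median absolute AUROC
gap is far below 0.15 — but both saturate near AUROC 1.0 because the
phantom classes are separable by construction. The qualitative
conclusion that tight boxes preserve the class signal is the property
being demonstrated; absolute performance numbers on phantoms say
nothing about clinical data.

## Known limitations

* The phantom model is statistical, not physical; acoustic artifacts
  that drive real segmentation difficulty (shadowing, reverberation,
  heel-toe contact) are absent.
* The cascade detector is reliable only on high-contrast lesions; for
  heavy speckle the external-detections route is the intended path.
* Class separability on phantoms saturates AUROC, so the mask-source
  comparison exercises the degradation direction only weakly at the
  default jitter level; increasing `external_jitter_sd` degrades the
  box-derived model monotonically.
* Benign subtype subclassification (cyst vs fibroadenoma) is out of
  scope, as are multi-lesion frames and 3D acquisition.
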