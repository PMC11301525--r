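---
title: "Two-stage segmentation of adnexal masses on ultrasound: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage segmentation of adnexal masses on ultrasound: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adnexseg)
```

## The problem

Adnexal masses — lesions of the ovary, fallopian tube, or surrounding
pelvic tissue — are assessed primarily on transvaginal ultrasound, where
the qualitative reading of mass morphology and echogenicity is expert-
dependent. A quantitative pipeline needs two things before any radiomic
feature can be extracted: (1) an outline of the mass within a
clinician-drawn bounding box, separating it from surrounding tissue, and
(2) a separation of the mass interior into its *relative* hypoechoic
(dark: fluid, cystic content, acoustic shadow) and hyperechoic (bright:
solid tissue, clot, septation) components.

`adnexseg` implements both stages:

* a supervised **U-net** that classifies every pixel of a standardized
  256×256 region of interest (ROI) as inside or outside the mass, followed
  by a fixed refinement chain that produces the final mask and boundary at
  original ROI scale; and
* an unsupervised **two-cluster fuzzy c-means (FCM)** that separates
  in-mass pixels using a three-channel texture stack: the original
  grayscale, a local-entropy filter, and a local standard-deviation
  filter, each computed over nine-pixel (3×3) sliding neighbourhoods.

Clinical ultrasound data cannot be redistributed, so the package ships a
seeded **speckle phantom generator** that emulates the relevant image
structure with per-pixel ground truth. Every stage is trainable and
testable end to end on phantoms alone.

## Coordinate and intensity conventions

All images are numeric matrices with intensities in $[0, 1]$; writers
quantize to 8-bit PNG. All coordinates are `(row, col)`, 0-based;
bounding boxes are half-open. Contours are ordered boundary-pixel lists:
the boundary is the set of foreground pixels with at least one
8-neighbour that is background or outside the image, ordered by a
clockwise Moore-neighbourhood trace. (For a filled 3×3 block inside a
larger image this yields the 8 border pixels — the centre pixel touches
only foreground.) Pixels the clockwise walk skips when it steps
diagonally are spliced back next to an adjacent traced pixel so that the
contour equals the boundary set exactly.

## The phantom generator

A phantom is a square canvas holding one lobulated elliptical mass:

* **Geometry.** An ellipse (semi-axes $a, b$, rotation $\theta$) with a
  sinusoidal radial perturbation $\rho \le 1 + A\sin(k\varphi + \phi)$
  (default $k = 3$ lobes, amplitude $A = 0.1$) produces non-trivially
  curved boundaries for Hausdorff-distance testing while remaining a
  single 4-connected, hole-free region.
* **Echo levels.** Background 0.45, hypoechoic interior 0.2, hyperechoic
  components 0.8 by default. The interior is hypoechoic except where a
  component layout (elliptical "solid" blobs, line-segment septations)
  marks it hyperechoic; the layout is also the per-pixel component truth.
* **Speckle.** Ultrasound speckle is multiplicative, so each pixel is
  multiplied by an i.i.d. unit-mean Gamma factor (shape 4 by default,
  i.e. a relative standard deviation of 0.5), optionally 3×3 box-blurred
  to mimic laterally correlated speckle. With speckle disabled the image
  is piecewise constant, which several exact tests rely on.
* **Acoustic shadows.** Selected column ranges are attenuated
  (default factor 0.4) from a starting row downward — by default from
  below the mass, or from inside it to emulate shadowing distal to an
  attenuating focus, the configuration used to probe how shadow pixels
  cluster.

Cohorts mirror a 54-mass study population: nine pathology-subtype
analogues (36 benign / 18 malignant by default), largest-remainder
apportionment so realized counts match the requested mixture exactly,
one patient in ~54 carrying two masses, and a bounding box with a random
2–10 px margin per side. Subtype profiles only condition geometry ranges
(blob counts and sizes, septation and shadow probability); the cohort
generator makes no claim of clinical echo-texture calibration — the
original study reports none, so all ranges are package defaults exposed
in `subtype_profiles()`.

What the phantoms deliberately do **not** model: beam physics
(point-spread function, depth-dependent attenuation and gain), Doppler
overlays, out-of-plane effects, and real anatomical clutter. Passing
phantom benchmarks therefore demonstrates that the pipeline's mechanics
are correct and well calibrated at desk scale, not that the reported
clinical accuracy transfers.

## Dataset preparation

* **Patient-level stratified split.** Within each subtype, patients are
  shuffled under a seed and assigned whole-patient to training until the
  subtype's training mass count first reaches
  $\lceil 0.65 \cdot n_s \rceil$. Because patients move as units the
  realized fraction overshoots the 65% goal — mirroring the behaviour of
  stratified splitting in small clinical cohorts. A patient with masses
  of several subtypes is assigned with the first subtype encountered and
  counted in all. Each subtype keeps at least one training mass, and at
  least one test mass when it is carried by two or more patients.
* **ROI standardization.** Crop to the bounding box, resample to the
  network size (bilinear for images, nearest-neighbour for masks so they
  stay binary) on a corner-aligned grid — resampling to the same size is
  exactly the identity, which makes the inverse mapping used by the
  refinement chain well defined.
* **Augmentation.** Exactly 12 samples per training pair:
  {identity, left–right flip, up–down flip} × {0°, 90°, 180°, 270°},
  enumerated in that nested order as `transform_id` 0–11. As group
  elements these 12 contain duplicates (the dihedral group has order 8),
  but 12 samples are emitted deliberately — the augmented training-set
  size is part of the training recipe being reproduced.

## The U-net

The architecture is the canonical encoder–decoder with skip connections:
per level two 3×3 same-padded convolutions with ReLU, 2×2 max pooling
down, 2×2 stride-2 transposed convolutions up, channel-doubling per
level, and a final 1×1 convolution to two classes with per-pixel softmax.
Training minimises unweighted per-pixel two-class cross-entropy with Adam
(learning rate 0.001, minibatch 12, up to 120 epochs by default) under
seeded shuffling; weights use He initialisation. The loss choice, depth
(4), base width (32), padding scheme and the absence of a validation
split are package decisions — the training recipe being reproduced
specifies only the optimizer, rate, epoch cap and batch size — and all
are exposed in `unet_config()`.

The network and its gradients are implemented in single-precision
Armadillo (im2col + BLAS `gemm`); the backward pass is verified against
finite differences in the test suite at a tiny configuration. For a
depth-1, 1-filter network the parameter count is hand-countable (120),
which pins the architecture wiring.

### Reduced profile

`unet_test_profile()` — 128×128 inputs, depth 2, 8 base filters, 3
epochs — is the configuration used by the package's own benchmarks. The
sizes were chosen so that a full benchmark (200 augmented training
phantoms, i.e. 2400 samples and 600 Adam steps) trains in a few minutes
on one CPU core; the epoch count sits well past the point where the
training loss plateaus on phantom cohorts (the loss falls by an order of
magnitude within the first two epochs), and stays under the 15-epoch cap
the benchmark allows itself. Phantom segmentation at this scale is
deliberately an easy task — the benchmark checks calibration of the
whole chain, not network capacity.

## Mask refinement

The prediction mask is refined in a fixed order: resample to the
original ROI shape (nearest-neighbour), fill interior holes (background
components not 4-connected to the border), smooth with a normalised
Gaussian kernel of window 15 px, threshold strictly above 0.5, keep the
largest 4-connected component, and trace the outline. Decisions worth
recording:

* **Sigma.** Only the 15-px window is prescribed; $\sigma =$ window/6
  (2.5 px) places ±3σ inside the window, the standard window↔sigma
  convention. Configurable.
* **What is smoothed.** The binary mask is smoothed, not the probability
  map, following the prescription literally; smoothing the probabilities
  is a defensible alternative and can be emulated by passing the
  probability map with a pre-threshold.
* **Border handling.** Mirror reflection, so masses touching the ROI
  edge are not eroded by the convolution.
* **Strict threshold.** `> 0.5` exactly; an isolated foreground pixel
  vanishes (the kernel's centre weight is ≈ 0.026).
* The Gaussian is separable, so the 2-D convolution is applied as two
  1-D passes — exactly equal to the normalised 2-D kernel.
* A final hole-fill after largest-component selection enforces the
  output invariant (hole-free, single component) even for adversarial
  inputs where thresholding a smoothed multi-component mask could
  re-open a cavity; for ordinary predictions it is a no-op.

## Evaluation metrics

For each test mass, with predicted and reference masks and their
contours:

* **DSC** $= 2|A \cap B| / (|A| + |B|)$.
* **HD**, the *average* Hausdorff distance: the symmetric mean of the
  two directed mean nearest-neighbour distances between boundary point
  sets. The max-of-directed-means variant is available behind a flag;
  the mean variant is the default because it is the common choice in the
  segmentation-evaluation literature this follows.
* **Deq** $= 2\sqrt{\text{area}/\pi}$, the diameter of the circle with
  the reference region's area.
* **RHD-D** $=$ HD/Deq, a dimensionless boundary error normalised by
  mass size; zero for identical outlines and invariant under rescaling
  both outlines and region (verified numerically to within a few percent
  — pixelisation of area and boundary introduces a small systematic
  difference between magnifications).

Distances are computed between boundary pixel centres; Deq from the full
reference region. One discretisation effect is worth knowing: for a mask
translated by one pixel, half of the boundary pixels coincide with the
reference, so the discrete average Hausdorff distance is ≈ 0.5 px, not
1 px.

Cohort summaries report the per-metric median with a 95% confidence
interval from a seeded percentile bootstrap of the median (2000
replicates by default); the CI method is a package decision, recorded in
the summary output.

## Component separation

For the in-mass pixels of the (expert or refined predicted) ROI mask:

1. Build the 3-channel stack — grayscale, 3×3 Shannon entropy (256
   uniform bins on $[0,1]$, matching 8-bit acquisition granularity; in
   bits, ceiling $\log_2 9 \approx 3.17$), and 3×3 sample standard
   deviation ($n-1 = 8$) — over the **full ROI** with mirror padding, so
   in-mask border pixels see their real image context; then restrict to
   in-mask pixels.
2. Z-score each channel over the clustered pixels (a constant channel is
   left at zero). Without standardization the entropy channel
   (0–3.17 bits) would dominate grayscale (0–1); whether the original
   standardized is unstated, so the choice is recorded here and in the
   output metadata.
3. Run FCM with $c = 2$ clusters, fuzzifier $m = 2$, tolerance $10^{-5}$
   on memberships, ≤ 300 iterations, seeded random row-normalised
   membership initialisation. The objective
   $J = \sum_i \sum_k u_{ik}^m \lVert x_i - v_k\rVert^2$ is recorded per
   iteration and checked non-increasing on every run (alternating
   minimisation guarantees it). A point coinciding with a centroid gets
   a one-hot membership; a cluster whose total membership vanishes keeps
   its previous centroid.
4. Hard-assign pixels to the max-membership cluster (ties to the lower
   index) and label the cluster with the lower mean **original
   grayscale** as the relative hypoechoic component, the other as
   hyperechoic. Labels depend only on relative brightness, never on
   cluster index, so the labeling is invariant to the initialisation
   seed on well-separated data. If one cluster empties, it is ranked by
   the grayscale coordinate of its centroid (de-standardised), with a
   warning.

"Two-level" clustering is read as $c = 2$ components, the prospective
choice stated with the method; a hierarchical two-stage FCM would be a
different algorithm and is not implemented.

### The rim band

In-mask pixels within ~1–2 px of the mass boundary have 3×3
neighbourhoods that straddle the edge, so their entropy and standard
deviation are high regardless of interior echogenicity, and they tend to
cluster hyperechoic. This is a real property of the method — clinical
use of the same feature stack shows mass rims labeled hyperechoic — and
it bounds the achievable per-component Dice against planted truth: on
default-size phantoms the hyperechoic component recovers at ≈ 0.95 with
the residual error confined to the rim (eroding the mask by two pixels
lifts it above 0.96). The component-recovery benchmark therefore uses
phantoms whose solid blob occupies a substantial fraction (~25%) of the
mass, a configuration representative of mixed cystic–solid masses, and
reports the median over both components' Dice values. Small solid
foci are correspondingly harder: their recovery is rim-dominated.

FCM with random membership initialisation can also land in a poor local
minimum when the two texture populations are very unbalanced (a small
blob in a large cyst); the single-initialisation behaviour is kept
because it is part of the procedure being reproduced, and the benchmark
records the objective trace so such runs are visible.

## Pipeline, seeds and determinism

`cmd_run_all()` chains simulate → split → train → segment → evaluate →
components, each stage writing its artifacts, a JSON-lines log entry
(stage, seed, wall time) and a configuration fingerprint used to skip
completed stages on re-runs. One global seed determines every draw:
cohort (seed), split (+1), network init/shuffling (+2), FCM (+3),
bootstrap (+4). Two runs with the same seed produce byte-identical
metrics tables on the same platform; across BLAS builds, training is
floating-point-sensitive, so cross-platform identity is not claimed —
the determinism check in the test suite runs the full pipeline twice at
a reduced size (10 masses, 64 px) purely because determinism is
independent of problem size.

## Problem sizes used by the package's own checks

* End-to-end benchmark: 200 training / 40 test phantoms at 128 px,
  reduced-profile network, 3 epochs (2400 augmented samples, 600 Adam
  steps).
* Component recovery: 20 phantoms at 256 px.
* Metric oracle comparisons: 50 random contour pairs up to 500 points.
* Determinism: full pipeline twice at 10 masses / 64 px.

## Known limitations

* The phantom texture model (piecewise-constant echogenicity ×
  Gamma speckle) has no spatial structure inside components beyond
  correlated speckle; real masses show gradients, layering and
  posterior enhancement that the FCM stage would see.
* The U-net profile is sized for CPU training on phantoms; clinical
  deployment would retrain the full-size default profile on real ROIs.
* RHD-D inherits ~2–3% pixelisation bias across scales; comparisons
  should use masses more than a few dozen pixels across.
* The stratified split guarantees at least one test mass per subtype
  only when the subtype is carried by two or more patients whose first
  subtype it is; rarer sharing patterns fall back to best effort.
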