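---
title: "Guideline-constrained standard-plane extraction from 3-D echocardiography"
author: "cardioplane"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guideline-constrained standard-plane extraction from 3-D echocardiography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cardioplane)
```

## The problem

A routine echocardiographic examination reads the heart through six standard
planes: the apical four-, three- and two-chamber views (A4C, A3C, A2C) and
three parasternal short-axis views at the mitral-valve, papillary-muscle and
apex levels (PSX MV, PSX PM, PSX AP). In 3-D echocardiography these planes
can be extracted automatically from a single volume. cardioplane implements
a three-stage pipeline that mirrors how the clinical guideline itself
prescribes finding the views:

1. **Landmark detection.** Three anatomical feature points — the LV apex and
   the septal and lateral extremes of the mitral annulus (MA) — are
   localized by per-landmark 3-D Hough forests with a coarse-to-fine
   hierarchical search.
2. **Plane initialization.** The A4C plane passes through the three
   landmarks. The LV long axis runs from the MA midpoint to the apex. A3C
   and A2C intersect A4C along that axis at fixed rotations (defaults 53°
   and 129°), and the three short-axis planes lie perpendicular to the axis
   at fixed fractions of its length (defaults 1/6, 3/6, 5/6, mitral valve
   basal).
3. **Constrained refinement.** Because individual anatomy deviates from the
   population regularities, each plane is refined by a regression forest —
   but only inside its anatomical constraint: apical planes rotate about the
   fixed long axis (one angle θ), short-axis planes translate along it (one
   signed distance γ). The axis itself is never refined; its direction is
   already determined accurately by the landmarks.

All geometry lives in world millimetres; volumes are axis-aligned grids with
`world = origin + index · spacing` (0-based indices, no direction cosines).

## Hough-forest landmark detection

Each landmark has its own forest. Training patches `(I_i, c_i, d_i)` carry
the local appearance `I_i`, a class label `c_i` (1 inside a bounding box of
half-width 10 mm around the true landmark, 0 elsewhere), and the voxel
offset `d_i` of the patch center from the landmark, so that a test voxel `p`
reaching a leaf votes for the landmark at `p − d` for every stored offset.
Appearance is five per-voxel channels: raw intensity, the three 3-D Sobel
responses, and the gradient magnitude. A node's binary test compares the
difference of two channel values at two in-patch offsets against a
threshold; thresholds are drawn uniformly over the empirical range of the
differences at that node.

Node splitting minimizes either the class-label uncertainty

> U1(A) = −|A| · Σ_c p(c|A) · ln p(c|A)

or the offset uncertainty (object patches only)

> U2(A) = Σ_i ‖d_i − d̄_A‖², c_i = 1,

the choice made uniformly at random per node (U1 is forced when fewer than
two object patches remain, where U2 is undefined). Leaves store the object
fraction `C_L` and the offset list `D_L` of their object patches. At test
time every voxel in the search region is routed down all trees; leaves with
`C_L ≥ τ` deposit weight `C_L / |D_L|` per offset into a vote accumulator,
which is Gaussian-smoothed (σ = 2 voxels) and read out at its argmax.

The coarse-to-fine search votes first over the whole volume block-mean
downsampled by 4, then restricts full-resolution voting to a cubic
neighborhood (half-width 16 mm) of the coarse detection. This cuts the
number of fine-level voxels examined by roughly two orders of magnitude
while leaving the detection at least as accurate — the coarse stage also
discards far-field structures that could attract spurious votes.

Operating point: 10 trees of maximum depth 15, leaf threshold τ = 0.95.
The sampling and voting knobs (50 positive + 50 negative patches per volume
per tree, 200 candidate tests × 10 thresholds per node, minimum 20 samples
per node, patch extents 15³ fine / 9³ coarse, voting strides 1 coarse /
2 fine) are desk-scale defaults, all configurable through `hough_config()`.
Each tree draws a fresh patch sample; per-tree seeds derive from the master
seed by fixed increments, so training is fully reproducible.

## Constrained plane refinement

The refinement frame puts the origin `O` at the volume center with the x–z
plane through `O` as angular reference; for angle refinement the working
reference is the plane through the long axis closest to the x–z plane (any
constant offset between the two cancels in the vote differences below).
The *sampling plane* of a voxel contains the voxel and the long axis (long
kind) or passes through the voxel perpendicular to the axis (short kind),
so each voxel is summarized by a single signed parameter: its angle θ_p
about the axis (folded to (−90°, 90°], planes being unoriented) or its
signed axial distance γ_p.

Training patches are positive when their sampling plane lies within
θτ = 10° / γτ = 5 mm of the ground-truth plane — the clinical maximum
permissible error — and negative in the surrounding (τ, 2τ] band. Each
patch stores its exact offset φ_i from the ground truth. Trees are grown
exactly as detection trees but score candidate splits with V1 (same form as
U1) or V2 (squared φ deviation over object patches); leaves store `C_L` and
the φ list of their positive patches only.

At test time, voxels whose sampling plane lies within (−2τ, 2τ) of the
initial plane are routed through the forest; each leaf with `C_L` above the
leaf threshold emits one vote `φ_t = φ_p − φ_i` per stored `φ_i` — an
estimate of the target plane's frame-relative parameter — with weight
`C_L`. The refined parameter is the `C_L`-weighted mean of the votes, which
by construction lies inside the emitted vote range; the output plane
realizes it as a rotation about the axis or a translation along it, so the
constraints hold exactly, by parametrization. If no leaf passes the
threshold the initial plane is returned with a warning.

Two numerical details matter here. First, θ values are computed on the
branch of the 180°-fold centered at the initial plane's own angle, so a
refinement band that straddles ±90° cannot be split by the fold. Second,
voxels are restricted to a region of interest derived from the axis
geometry (within 40 mm of the axis line, axial fractions −0.1 to 1.05):
voxels far outside the ventricle carry no information about the plane
offset, and their votes would only dilute the estimate. Defaults (10 trees,
depth 15, 150 + 150 patches per volume per tree, 300 candidate tests,
minimum 12 samples, patch extent 21³, voxel stride 2 in the band) sit in
`refine_config()`. The leaf threshold for refinement defaults to 0.95 like
the detector's; it is a coverage/purity trade-off and exposed in the
configuration.

## The synthetic phantom

`generate_phantom()` builds a left ventricle as a truncated-ellipsoid
myocardial shell (bright) around a blood pool (dark) on mid-gray
background, tilted against the grid axes, with three classes of anatomical
detail that the pipeline's observability depends on:

- a brighter mitral-annulus ring at the base, whose extremes along the A4C
  direction define the septal and lateral MA landmarks;
- two papillary-muscle protrusions on the endocardial wall at mid-cavity —
  the defining feature of the PSX PM level. Without them (and the banding
  below) the shell is locally translation-invariant along the axis near the
  equator, and a short-axis plane's position would be unobservable in
  principle at millimetre scale;
- a deterministic axial intensity banding of the myocardium (relative
  amplitude 0.15, period 22 mm) emulating the layered, trabeculated texture
  of real myocardium.

Multiplicative Gaussian speckle (amplitude 0.15) provides the stochastic
texture. Ground truth is recorded exactly: the landmarks by construction,
the planes by the guideline initialization, optionally perturbed per plane
(θ ~ U(−8°, 8°) for apical planes, γ ~ U(−4, 4) mm for short-axis planes)
to emulate the individual variation that makes refinement necessary;
perturbations are recorded in the truth object. Defaults are a 128³ grid at
1 mm spacing, 80 mm base-to-apex length and a ~31 mm MA diameter.

Data augmentation follows the standard augmentation protocol: five patterns per volume
with per-axis rotations uniform in (−20°, 20°) and per-axis scales uniform
in (0.8, 1.2), resampled trilinearly. Landmarks are mapped exactly;
truth planes are rebuilt by the guideline construction on the transformed
landmarks (with the recorded jitter re-applied) because an affine image of
a plane set does not generally preserve the axis constraints under
anisotropic scaling — plane normals transform by the inverse transpose.

Noise emulates degraded image quality: the base field is zero-mean Gaussian
with variance 0.01 on range-normalized intensity — a 10% relative amplitude
— and the level scales it linearly, so level L adds noise with
`sd = (L/100) · (max − min)`. Level 0 returns the input bitwise-unchanged.

**What the phantom does not emulate.** There is no point-spread-function
convolution, no attenuation or shadowing, no probe geometry, no cardiac
motion, and no pathology; anatomy is fixed up to the configured parameters
while real hearts vary continuously in shape. Passing the phantom
experiments therefore demonstrates that the learning machinery recovers
what the images encode — not clinical-grade performance, which can only be
established on real recordings.

## Validation experiments

The test suite validates the pipeline at desk scale on 64³ phantoms at 2 mm
spacing (the generator's default anatomy at half resolution — relative
geometry, bands and thresholds unchanged):

Two phantom populations are used. Detection and noise experiments draw from
a *population-varied* generator (short half-axis 22–27 mm, long half-axis
40–46 mm, wall 7–9 mm, tilt 2–12°), emulating inter-individual anatomy;
the refinement recovery is a *controlled* experiment on the fixed default
anatomy, where the planted offset is the only initialization error.

- **Detection recovery.** Forests at the reference operating point (10
  trees, depth 15, τ = 0.95) trained on 20 phantoms, evaluated on 10
  held-out phantoms: pooled mean landmark error under 5 mm, and the
  hierarchical search must examine strictly fewer fine-level voxels than
  exhaustive single-scale voting without increasing the mean error.
- **Refinement recovery.** Refiners trained on 20 unperturbed phantoms; on
  10 held-out phantoms, planted perturbations uniform in (−2θτ, 2θτ) /
  (−2γτ, 2γτ) must be recovered with mean absolute residual below θτ/2 =
  5° and γτ/2 = 2.5 mm, and must improve on the initialization on average.
  Two planes per kind are probed: A4C and A2C (near-zero and large
  reference angles, exercising the frame bookkeeping), PSX PM (the most
  locally ambiguous level) and PSX AP. These runs use phantoms without
  ground-truth jitter: the planted offset is the controlled variable, and
  annotation-style jitter is invisible in the image by construction, so it
  could only blur the measurement.
- **Constraint preservation.** Every refined apical plane still contains
  the axis and every refined short-axis plane keeps the axis normal —
  checked exactly over all refinement trials.
- **Noise robustness.** One model set trained on 8 phantoms at noise levels
  0/10/20% together (training on clean and noisy copies together), evaluated end-to-end on 10
  held-out phantoms per level. The asserted robustness scalar is the
  criterion-normalized plane error — the mean over all six planes of
  (angle/10° + distance/5 mm)/2 — which must be non-decreasing in the noise
  level, and the mean apical angle and short-axis distance must remain
  inside the 10°/5 mm criterion at 10%. A single pooled scalar is used
  because at desk scale the pipeline is accurate enough (apical angle
  errors around a degree) that individual error columns can tie between
  adjacent noise levels while the pooled error still trends.
  This experiment uses unperturbed truth so that the measured
  errors reflect image quality rather than an annotation-jitter floor
  (jittered truth is invisible in the image by construction and floors
  every error column at the mean jitter).
- **Formula oracles.** The split uncertainties and the vote accumulator are
  checked against brute-force re-evaluation (enumerated patch sets;
  exhaustive voxel-by-leaf loops on ≤16³ volumes), and the agreement
  statistics against closed-form hand cases.

## Design choices and numerical conventions

- **Offsets and votes.** Stored detection offsets are
  `d = center − landmark`, so the voting rule `p − d` lands on the
  landmark; the two orientations are easy to confuse and the reflected
  variant fails loudly (votes scatter away from the target).
- **Vote aggregation.** The refined parameter is the `C_L`-weighted mean
  `Σ φ_t · C_L / Σ C_L`. Normalizing by the raw vote count instead (the
  other reading of the formula) shrinks the estimate toward the arbitrary
  reference plane whenever `C_L < 1`, with a bias proportional to the
  frame-relative magnitude of the target — measurably degree-scale for
  planes tens of degrees from the reference. The weighted mean is also what
  makes the estimate respect the vote range.
- **Normal signs.** Planes are orientation-free for all error metrics
  (angles fold via `acos(|n₁·n₂|)`); construction fixes signs by the
  right-hand rule on (septal − apex, lateral − apex) and rotations are
  right-handed about the base→apex direction, with a configurable sign
  flip.
- **Tie-breaks and degeneracies.** Vote-map argmax ties resolve to the
  first voxel in array storage order. Landmark triples must span a triangle
  of area > 1 mm²; three-point plane construction uses a scale-relative
  collinearity test. Voxels within 2 mm of the axis line have no
  well-defined long-kind sampling plane and are excluded. Out-of-volume
  channel reads clamp to the edge voxel, so every voxel can vote.
- **Serialization.** Models are single-file RDS payloads with a format tag,
  version, config block and flattened node arrays; readers reject foreign
  or newer files.

## Limitations

- The phantom's appearance–position relationship is far cleaner than real
  ultrasound; expected errors on clinical data are substantially larger
  (the useful observable here is the *behavior* of the method — error
  orderings, constraint preservation, robustness trends).
- Refinement accuracy degrades for initial errors approaching the edge of
  the (−2τ, 2τ) band, where part of the voting region shows appearance
  outside the training bands; the vote-purity filter suppresses but cannot
  eliminate those votes.
- Volumes must be axis-aligned (no direction cosines) and the long axis
  must not be parallel to the reference-plane normal (y axis); the frame
  construction errors out in that degenerate configuration.
- Only planar reformats are supported, and the long axis is fixed during
  refinement by design.
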