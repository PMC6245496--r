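# cardioplane

Automatic extraction of the six cardiac standard planes from 3-D
echocardiographic volumes: the apical four-, three- and two-chamber views
(A4C, A3C, A2C) and the parasternal short-axis views at mitral-valve,
papillary-muscle and apex level (PSX MV, PSX PM, PSX AP). The package is
aimed at researchers in cardiac image analysis who want a fast,
CPU-friendly, fully reproducible baseline for standard-plane extraction —
and a self-contained synthetic test bed: a left-ventricle phantom generator
with exact ground truth means the entire pipeline trains and validates
without any external dataset.

## Method

The pipeline follows the anatomical regularities that clinical guidelines
use to define the views, one learning stage per guideline step:

1. **Landmark detection** — per-landmark 3-D Hough forests localize the LV
   apex and the septal and lateral mitral-annulus (MA) points. Training
   patches `(I_i, c_i, d_i)` store appearance, an object/background label,
   and the voxel offset `d_i` from the landmark; node splits minimize either
   the class-label uncertainty `U1(A) = -|A| Σ_c p(c|A) ln p(c|A)` or the
   offset uncertainty `U2(A) = Σ_{c_i=1} ||d_i - d̄_A||²`, chosen at random
   per node. Leaves keep the object fraction `C_L` and offset list `D_L`;
   at test time every voxel `p` reaching a leaf with `C_L ≥ τ` votes at
   `p - d` with weight `C_L/|D_L|`, and the landmark is the vote-map argmax.
   A coarse-to-fine search votes on a 4× downsampled volume first, then
   only in a 16 mm neighborhood of the coarse hit at full resolution.
2. **Plane initialization** — A4C through the three landmarks; the long
   axis from the MA midpoint to the apex; A3C and A2C rotated about the
   axis by 53° and 129°; short-axis planes perpendicular to the axis at
   fractions 1/6, 3/6 and 5/6 of its length.
3. **Constrained refinement** — per-plane regression forests refine a
   single parameter φ(θ, γ): a rotation θ about the fixed axis for apical
   planes, a signed translation γ along it for short-axis planes. Patches
   within θτ = 10° / γτ = 5 mm of the true plane are positive, the
   surrounding (τ, 2τ] band negative; leaves store `C_L` and the exact φ
   offsets of their positives. Voxels within ±2τ of the initial plane vote
   `φ_t = φ_p - φ_i` (weight `C_L`), and the refined plane realizes the
   weighted vote mean. The axis constraints hold exactly by parametrization.

See the methods vignette (`vignettes/standard-plane-extraction.Rmd`) for
the full model description, parameter table, phantom design and
limitations.

## Worked example

Train a small model set on four synthetic phantoms and extract the planes
of an unseen one:

```r
library(cardioplane)

spec <- function(seed) phantom_spec(shape = c(48, 48, 48), spacing = 2,
                                    short_axis_mm = 20, long_axis_mm = 34,
                                    wall_mm = 7, jitter_theta_deg = 4,
                                    jitter_gamma_mm = 2, seed = seed)
train <- lapply(1:4, function(i) generate_phantom(spec(i)))

models <- train_pipeline(
  lapply(train, `[[`, "volume"), lapply(train, `[[`, "truth"),
  hough_cfg = hough_config(n_trees = 4, max_depth = 10, n_pos = 40,
                           n_neg = 40, min_samples = 8, n_tests = 100,
                           patch_half_coarse = 3),
  refine_cfg = refine_config(n_trees = 4, max_depth = 10, n_pos = 60,
                             n_neg = 60, min_samples = 8, n_tests = 100,
                             roi_radius_mm = 35),
  seed = 7)

case <- generate_phantom(spec(99))
res <- extract_planes(case$volume, models)
res$landmarks
#>   apex       (   48.00,    42.00,    80.00) mm
#>   septal_ma  (   60.00,    50.00,    20.00) mm
#>   lateral_ma (   34.00,    50.00,    20.00) mm

ev <- evaluate_planes(res$planes, case$truth$planes, case$truth$axis)
print(ev[, c("plane", "angle_deg", "distance_mm", "success")], digits = 3)
#>    plane angle_deg distance_mm success
#> 1    A4C      2.13      0.5825    TRUE
#> 2    A3C      3.17      0.7480    TRUE
#> 3    A2C      4.03      0.0384    TRUE
#> 4 PSX_MV      1.03      1.2202    TRUE
#> 5 PSX_PM      1.03      2.0513    TRUE
#> 6 PSX_AP      1.03      0.6243    TRUE
```

Each row compares an extracted plane with the phantom's ground truth: the
folded dihedral angle in degrees, the distance (mm) from the LV center's
projection on the true plane to the extracted plane, and whether the plane
meets the clinical success criterion (angle < 10° and distance < 5 mm). On
this seeded case all six planes succeed — the detected landmarks sit within
about a voxel of the truth, the guideline initialization carries them into
six planes, and refinement pulls each plane back toward the (deliberately
perturbed) individual ground truth.

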