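---
title: "Synthetic CT generation and dosimetric validation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic CT generation and dosimetric validation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

MRI-only radiotherapy planning replaces the planning CT with a *synthetic CT*
(sCT): a Hounsfield-unit (HU) volume estimated from MRI, so that dose can be
calculated without a CT scan and without CT-to-MRI registration error.
`pelvisct` implements four widely used sCT generation families for the
pelvis — bulk density assignment, tissue-class density assignment, hybrid
multi-atlas fusion, and a conditional GAN — together with the validation
machinery used to compare them against a reference CT: HU mean error (ME)
and mean absolute error (MAE) with end-slab exclusion, a simplified
attenuation dose engine, DVH metrics, ICRU-point and DVH percentage dose
differences, 3D gamma analysis, and Mann-Whitney cohort statistics.

Clinical paired CT/Dixon-MRI pelvis scans cannot be redistributed, so the
package ships a fully synthetic, seeded digital pelvis phantom module. Every
experiment in the test suite and the acceptance script runs end-to-end on
phantom cohorts with exact ground truth.

## The phantom module

`phantom_spec()` / `generate_phantom()` render a parametric pelvis:
an elliptical body cylinder with a subcutaneous fat rind (12 mm by
default), muscle/viscera interior, a sacrum and two lateral hip bones
(cortical shell around a marrow core), a bladder, a rectal tube with an
optional gas pocket, and a PTV enclosing the rectum. Anatomy is
geometric (ellipsoids and tubes) rather than image-derived: this keeps the
module self-contained and makes the ground-truth label map exact, at the
cost of realism in organ texture and boundary irregularity.

Default tissue HU means (fat -100, muscle 45, cortical bone 800, marrow
250, bladder 15, gas -1000) are textbook-typical values and are
configuration, not estimates. The Dixon channels are synthesized from
per-class fat/water signal means with the channel identities in-phase =
water + fat and out-of-phase = |water - fat| holding exactly before noise.
Marrow is modelled as water-dominant (red marrow predominates in the adult
pelvis), which also keeps the fat-fraction segmentation well-posed. A
multiplicative bias field — the exponential of a centred random polynomial
of degree <= 2, amplitude-limited to the configured fraction — is applied
to the MRI channels only. `noise_sd["ct"]` scales the per-class HU standard
deviations (so 0 renders exact class means) and `noise_sd["mri"]` is an
absolute Gaussian sigma on the unit-scale MRI channels.

`generate_cohort()` creates inter-subject variability by scaling each
structure's semi-axes by U(1 ± 0.08), shifting centres by up to 4 mm and
scaling tissue means by U(1 ± 0.03); these half-ranges were chosen once as
plausible anatomical variability for adult pelves and produce cohorts whose
mean body volume stays within 10% of the base rendering.
`warp_phantom()` applies a smooth random displacement field (a sum of four
random Fourier modes per component with wavelengths of at least the
`smoothness` parameter, rescaled so the maximum displacement equals
`amplitude`); Fourier modes rather than smoothed white noise keep typical
displacements comparable to the maximum, so a "5 mm warp" really moves
anatomy by several millimetres.

What passing phantom tests does *not* show: performance on real anatomy
with partial-volume boundaries, organ texture, susceptibility or motion
artefacts, or contrast agents. The phantom validates the *machinery* —
segmentations, registrations, fusion rules, dose and gamma arithmetic — not
clinical accuracy.

## Density calibration

Dose engines consume relative electron density (RED). The density-assignment
methods specify REDs, so the stored sCT HU depends on a calibration curve.
The default `density_calibration()` is the two-segment piecewise-linear
curve (-1000 HU, RED 0.00) - (0, 1.00) - (1500, 1.85): air at zero, the
water anchor at (0, 1), and a flatter bone branch, the standard shape of a
clinical CT calibration. Under it the bulk soft-tissue RED 0.97 maps to
-30 HU and bone RED 1.20 to 352.9 HU. Any site curve can be substituted as
a two-column (HU, RED) table; the curve must be strictly increasing, so the
map is a bijection on its range.

`override_bowel_gas()` replaces each connected in-body pocket below
-200 HU with the mean HU of non-gas voxels within a 10 mm shell around the
pocket. The neighbourhood definition is ours: replacement per connected
component (not per voxel) keeps the fill value stable across a pocket, and
10 mm captures local tissue without reaching distant structures. The
operation is idempotent.

## Classic sCT methods

`assign_bulk_density()` writes two classes (bone RED 1.20 / soft tissue
0.97), `assign_tissue_class()` three (bone 1.16, muscle/viscera 1.02, fat
0.91), through the calibration above. Bone is an *input* mask (the clinical
workflow outlines it manually on in-phase Dixon); the phantom supplies its
ground-truth bone mask. The body contour comes from `segment_body()` —
Otsu thresholding of the in-phase image, largest connected component, holes
filled; whether the original thresholding was manual is unknown, so the
automatic strategy is the default with a numeric manual override. Fat comes
from `segment_fat()` — fat fraction F/(F+W) > 0.5; the threshold value is
not published, 0.5 is the natural split. Voxels whose total Dixon signal is
below 25% of the in-body median are excluded because fat fraction is
noise-dominated there (cortical bone, gas). Class precedence is bone > fat
> muscle; muscle/viscera is the Boolean remainder of the body.

## Hybrid multi-atlas

`multi_atlas_sct()` chains: bias correction, per-pair structure-guided
registration, CT propagation, local weighted voting.

*Bias correction* (`correct_bias_field()`) fits a polynomial of total
degree <= 3 to log intensity inside the body by iteratively reweighted
least squares with a Tukey biweight. The robust weighting makes the fit
track the dominant soft-tissue surface and ignore bone/gas outliers, so on
bias-free input the estimated field is within ~1% of unity while a 20%
quadratic bias is removed almost entirely.

*Registration* (`register_atlas_to_target()`) is rigid-then-deformable,
driven by masks and intensity. The 6-DoF rigid stage initializes from
body-mask centroids and refines rotation + translation by Nelder-Mead on
the SSD between Gaussian-smoothed masks (body, bone, bladder); it aborts
when the aligned body Dice is below 0.5. The deformable stage is a
multi-resolution demons iteration whose similarity combines the water
channel intensity with smoothed binary label channels (bone, bladder) at
weight 0.5 each — the guidance structures are the contract; any engine
meeting the recovery post-conditions would be conformant. Updates are
fluid-smoothed (sigma 6 mm), the accumulated field elastic-smoothed
(3 mm), per-iteration displacement capped at one voxel. The rigid and
demons transforms are composed analytically so the original atlas volumes
are resampled exactly once (linear for images/CT, nearest for masks).

*Fusion* (`local_weighted_voting()`): per voxel, the dissimilarity to
atlas *i* is the mean squared intensity difference over a cubic patch of
radius 2 voxels; weights are `exp(-gain * d_i / sigma2)` with `sigma2` the
in-body target intensity variance and gain 10 by default. The exact weight
function and gain/radius values used originally are not published; this
exponential-of-scaled-MSD form is the common choice in patch-based label
fusion, and both parameters are configuration. Weights are computed
relative to the per-voxel best-matching atlas — a common factor that
cancels in the normalization — so the weight sum lies in [1, n] and cannot
underflow; the degenerate zero-variance target falls back to the
unweighted mean, with the count reported. The fused value is a convex
combination of the propagated CTs by construction.

## Conditional GAN

The cGAN translates in-phase MRI slices to CT slices. The generator is an
encoding-decoding U-Net: 3x3 stride-1 conv blocks and 3x3 stride-2
down-sampling convs (batch norm + ReLU), widths doubling over four stages
to a 16x-base bottleneck; the decoder mirrors with 3x3 stride-2 transpose
convs and encoder skip concatenations; a 1x1 conv + tanh emits the slice.
Dropout 0.5 follows the bottleneck and the widest decoder block. The
discriminator is CD8-CD16-CD32-CD64-CD128 (3x3 stride-2 conv + batch norm
+ leaky ReLU 0.2), a 1x1 C128 block, then a fully connected sigmoid on the
(MRI, CT-or-sCT) pair. Training alternates discriminator (binary
cross-entropy, real vs fake pairs) and generator (BCE-to-real + L1, both
weighted 1) updates with Adam at learning rate 1e-4, batch size 10,
weights initialized N(0, 1e-4).

No deep-learning framework is available to R here, and the network is part
of the package's subject matter, so the layers, backpropagation and Adam
are implemented in package code (strided-slice matrix products against
BLAS). Every backward pass is validated against finite differences in the
test suite, and training is bit-deterministic for a fixed seed because all
randomness flows through R's RNG.

Two profiles exist. The full-scale profile (320x320 slices, base 64
filters, 20 epochs) matches the published recipe and is configuration-
selectable. The desk profile — the package default — runs 64x64 slices
with filter counts scaled by 1/4 and 5 epochs, sized to train in about a
minute on one CPU. Slices are axial; the L1 loss is computed full-frame
(background is zeroed by masking, so the distinction is minor) — both
choices are stated because the original is ambiguous. Preprocessing zeroes
the background, aligns the dominant in-body intensity mode across cases (a
piecewise-linear peak standardization; exactly scale-invariant), and maps
both channels affinely to [-1, 1]; the CT mapping over [-1000, 1500] HU is
inverted exactly at prediction. At desk scale the 20 Adam steps of the
smoke run move the near-zero-initialized generator only slightly, so
training-phantom MAE sits near 250 HU; the smoke test freezes a 300 HU
bound from that oracle run and asserts the strict first-to-last epoch L1
decrease, which is the learning signal the desk profile is meant to show.

## Dose engine

`calculate_dose()` is deliberately *not* a clinical dose algorithm; it
stands in for the treatment planning system so that dose becomes a
deterministic, HU-sensitive functional of the sCT. `n_beams` equally
spaced coplanar parallel beams (default 36, a VMAT-arc surrogate) deposit
`exp(-mu_eff * d_rad)` in every voxel inside a rectangular aperture around
the PTV projection (margin 10 mm), where the radiological depth `d_rad` is
the exact Siddon-style path integral of RED in mm from the body surface
along the ray. `mu_eff` defaults to 0.006/mm, an effective 6-MV-like
attenuation. No scatter, build-up or inverse-square modelling. The
normalization factor that delivers the prescription at the isocenter on
the reference CT is frozen and reused for the paired sCT run — the
"identical monitor units" convention — so dose differences reflect HU
differences only. On a uniform slab the engine matches the exponential
closed form to within discretization error, and dose is exactly linear in
the normalization.

DVH metrics use the at-least-coverage convention with linear interpolation
between sorted voxel doses (`quantile` type 4): `Dx` is the dose received
by at least x% of the structure, so two equal halves at 40/60 Gy give
D50 = 40 Gy; `Vy` is the volume fraction at or above y% of prescription.
The D98/D95/D50/D2/V95 set is our choice of "standard" parameters; the
set is an argument. Percentage dose difference is
`(D_sCT - D_CT) / D_CT * 100`, negative when the sCT is cold, and
multi-parameter DVH comparisons are averaged per structure and then across
structures.

## Gamma analysis and cohort statistics

`gamma_3d()` evaluates, for each reference voxel above the low-dose
threshold inside the eroded body, the minimum over nearby points of
`sqrt((dose difference / DD)^2 + (distance / DTA)^2)`, with the evaluated
dose trilinearly interpolated on a candidate grid of step DTA/10 within a
search radius of 3 DTA. Candidates are visited in order of increasing
distance with an early exit once the distance term alone exceeds the
current minimum — an optimization that provably cannot change the result,
and that the test suite verifies bitwise against a plain-R exhaustive
search on random dose pairs. Normalization is *global*: DD is a percentage
of the maximum reference dose inside the eroded body (the original
normalization is unstated; this choice is explicit and configurable).
Erosion uses a spacing-aware spherical element of radius 15 mm, and the
default low-dose threshold is 10%. The comparison is asymmetric; the
CT-plan dose is always the reference. Pass rates at 3%/2 mm, 2%/2 mm and
1%/1 mm are monotone in the criteria by construction.

`mann_whitney_u()` computes U with ties counted one half. For
min(n, m) <= 8 without ties the two-sided p-value comes from the exact
null distribution, built by the classical counting recursion (equivalent
to full enumeration of all rank arrangements); otherwise a normal
approximation with tie and continuity corrections is used, and the result
records which path was taken. Cohort tables summarize percentage dose
differences as median and IQR (25th/75th percentiles, linear
interpolation — the estimator is stated because published IQR pairs rarely
say) and gamma / HU-error metrics as mean ± SD, with SD reported as 0 for
a single case.

## Problem sizes and numerical choices

The shipped experiments run on 28 x 44 x 44 voxel phantoms at 5 mm
spacing (small enough that a six-case leave-one-out atlas experiment —
thirty registrations — completes in a few minutes on one CPU) and the cGAN
desk profile described above; both sizes are package choices and scale up
by configuration. Trilinear interpolation clamps at grid boundaries except
inside the gamma search, where out-of-grid candidates are skipped rather
than extrapolated. Degenerate inputs fail loudly: empty masks, constant
volumes, isocenters outside the body, gas pockets with no tissue in reach,
and rigid alignments below 0.5 body Dice are all errors, not silent
results.

## Known limitations

The dose engine's simplifications mean absolute dosimetric numbers are not
clinically meaningful; only CT-vs-sCT *differences* under identical beam
geometry are. Phantom cohorts lack the anatomical and intensity complexity
that drives errors in real multi-atlas and deep-learning sCT, so published
clinical error magnitudes cannot be reproduced here and are not targets.
The desk-profile cGAN demonstrates the training loop, not converged image
quality; the full-scale profile exists but needs hours of CPU time.
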