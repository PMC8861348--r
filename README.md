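# pelvisct

Synthetic CT (sCT) generation and dosimetric validation for MRI-only
pelvic radiotherapy planning, in R.

MRI-only planning replaces the planning CT with an sCT — a Hounsfield-unit
(HU) volume estimated from MRI — so dose can be calculated without a CT and
without CT-to-MRI registration error. `pelvisct` implements the four
standard sCT generation families for the pelvis and the full validation
toolkit used to compare them against a reference CT:

* **Bulk density assignment** — two classes: bone at relative electron
  density (RED) 1.20, soft tissue at 0.97.
* **Tissue-class density assignment** — Dixon-based segmentation into fat
  (RED 0.91), muscle/viscera (1.02) and bone (1.16).
* **Hybrid multi-atlas** — bias-field correction, structure-guided rigid +
  deformable (demons) registration of each atlas MRI to the target, CT
  propagation and local weighted voting (LWV): per voxel,
  `w_i = exp(-g * d_i / sigma^2)` with `d_i` the patch mean-squared
  intensity difference to atlas *i*, fused as `sum(w_i CT_i) / sum(w_i)`.
* **Conditional GAN** — a U-Net generator (3x3 convs, stride-2
  down/up-sampling, skip connections, tanh output) against a
  CD8–CD128 convolutional discriminator, trained with adversarial + L1
  losses (weights 1/1) by Adam at learning rate 1e-4; implemented from the
  linear algebra up in package code and verified against finite
  differences.

Validation follows the standard MRI-only commissioning quantities: HU mean
error and mean absolute error with a 30 mm end-slab exclusion; a
deterministic multi-beam attenuation dose engine (an explicit TPS
surrogate, not a clinical algorithm) with frozen "monitor units" between
the CT and sCT runs; DVH metrics (D98/D95/D50/D2, V95); percentage dose
difference `(D_sCT - D_CT)/D_CT * 100`; 3D gamma analysis at 3%/2 mm,
2%/2 mm and 1%/1 mm with 15 mm body-perimeter erosion and a 10% low-dose
threshold (`gamma = min sqrt((dd/DD)^2 + (dist/DTA)^2)`, verified bitwise
against an exhaustive brute-force search); and Mann–Whitney U statistics
(exact by enumeration for small samples).

Clinical paired scans cannot be shared, so the package ships a seeded
digital pelvis phantom module (`generate_phantom()`, `generate_cohort()`,
`warp_phantom()`) producing paired pseudo-CT / pseudo-Dixon-MRI cases with
exact ground-truth labels, masks, reference point and prescription; every
experiment below runs end-to-end on phantoms.

## Worked example

```r
library(pelvisct)

# a 2-case phantom cohort with rectal gas, 28 x 44 x 44 voxels at 5 mm
spec <- phantom_spec(grid_shape = c(28L, 44L, 44L), spacing = c(5, 5, 5),
                     gas_pocket = TRUE)
cohort <- generate_cohort(spec, n = 2, seed = 11)

res <- run_experiment(cohort, methods = c("bulk", "tissue_class"))
subset(res$summary, metric %in% c("icru_point", "pass_3_2",
                                  "mae_whole_body"),
       select = c(method, metric, center))
#>        method         metric     center
#>          bulk     icru_point   2.841088
#>          bulk mae_whole_body 106.956512
#>          bulk       pass_3_2  99.350210
#>  tissue_class     icru_point   1.657144
#>  tissue_class mae_whole_body  61.948823
#>  tissue_class       pass_3_2  99.916372
```

Reading: on this synthetic cohort the tissue-class sCT roughly halves the
whole-body MAE relative to bulk assignment (62 vs 107 HU — most of the
residual is the piecewise-constant approximation of bone) and both
methods agree with the CT dose to within 3% at the ICRU point, with
3%/2 mm gamma pass rates above 99%. `res$metrics` holds the per-case
values; percentage-dose-difference metrics are summarized as median (IQR),
gamma and HU metrics as mean ± SD, mirroring the usual cohort-table
layout.

The single-method building blocks are exported too — `segment_body()`,
`segment_fat()`, `assign_bulk_density()`, `assign_tissue_class()`,
`multi_atlas_sct()`, `train_cgan()` / `predict_sct()`,
`calculate_dose()`, `dvh_metrics()`, `gamma_3d()`, `hu_error()`,
`mann_whitney_u()` — and all volumes read/write NIfTI via
`read_volume()` / `write_volume()`. See `vignette source
vignettes/methods.Rmd` for the models, parameter meanings and design
decisions.

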