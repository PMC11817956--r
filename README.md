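# neuroseg

Feasibility tooling for segmenting and **detecting small metastatic brain
tumors** in 3D MRI when only a handful of labeled cases exist.  A small
tumor is one whose largest per-slice area across all axial slices is below
3.5 cm²; such lesions span only a few pixels after resampling to the
canonical 128×128×64 tensor, which makes their Dice scores systematically
low even for useful models — the package quantifies that bias and evaluates
detection (sensitivity/specificity) alongside overlap.

The package provides, end to end and fully tested on a bundled synthetic
brain-phantom generator (no downloads, no GPU):

* **Synthetic cohorts** — clinical-style axial T2-FLAIR series with
  DICOM-style grayscale metadata (rescale slope/intercept, window
  center/width), polygon tumor annotations keyed by slice UID,
  white-matter-hyperintensity confounders, and challenge-style labeled
  volumes with labels {0, 1, 2, 4}.
* **Preprocessing** — the DICOM grayscale chain (modality LUT
  `v = m·v_org + b0`; VOI LUT, a piecewise-linear window with slope
  `g_m/w`; 12-bit presentation normalization), polygon rasterization,
  slice decimation `u_i = s_{16+2i}` (155 → 64 slices), label merging,
  cubic slice interpolation for thin stacks, zero-padding and in-plane
  resampling to 128×128×64.
* **Models** — a residual 3D U-net (stride-1 stem to 16 channels, four
  stride-2 residual encoder blocks, 256×8×8×4 bottleneck) and a
  Swin-transformer-style network (patch embedding + four patch-merging
  stages with W-MSA/SW-MSA attention pairs, 768×4×4×2 bottleneck,
  five-block convolutional decoder ending at 48×128×128×64), both written
  from first principles with compiled convolutions and hand-verified
  backpropagation, both scale-configurable so desk-scale variants preserve
  every shape contract.
* **Training strategies** — supervised learning with and without geometric
  augmentation (rotation ±20–50°, scale 0.6–0.9 / 1.1–1.5, shear 0.4, at
  rates 1/4/8/16/32), transfer finetuning, layer freezing (bottom two
  decoder blocks + head), and self-supervised pretraining with dual cutout
  views (6 inner crops 5–32 px, 6 outer crops 20–64 px), an NT-Xent
  contrastive term (`loss = ln(2N−1)` at the identical-embedding point)
  plus an L1 reconstruction term, followed by frozen-encoder downstream
  training.
* **Evaluation** — Dice `2TP/(2TP+FP+FN)`, connected-component case-level
  detection, cohort sensitivity/specificity (with and without
  hyperintensity cases), and the offset-square size-bias study.

## Worked example

```r
library(neuroseg)

# generate four small-tumor phantom cases and preprocess them
cohort <- generate_cohort(n_large = 0, n_small = 4, n_normal_plain = 0,
                          n_normal_hyper = 0, seed = 42, in_plane = 128)
cases <- lapply(cohort, function(cs)
  preprocess_clinical_case(cs$series, cs$annotations))
cases[[1]]
#> <canonical_case> 1.2.826.0.1.synthetic.2035301
#>   shape: 128x128x64  size_class: small  native max slice area: 1.39 cm^2

# train a desk-scale U-net with rate-4 augmentation on three cases,
# score the held-out fourth (a few minutes on one CPU)
cfg <- train_config("supervised_aug", model_spec = unet_spec(base_channels = 2),
                    epochs = 2, augmentation_rate = 4, seed = 1)
fit <- run_strategy(cases[1:3], cases[4], cfg)
fit$scores
#> # A tibble: 1 × 4
#>   case                          size_class    dice detected
#>   <chr>                         <chr>        <dbl> <lgl>
#> 1 1.2.826.0.1.synthetic.2059058 small      0.00863 TRUE
```

The held-out small lesion is *detected* (a predicted component overlaps a
real lesion region) while its Dice is still tiny — the few-pixel regime in
which overlap scores punish small objects.  The size-bias study makes that
analytic:

```r
dice_offset_study(c(3, 5), offset = 1)
#> # A tibble: 2 × 2
#>    size  dice
#>   <dbl> <dbl>
#> 1     3 0.444
#> 2     5 0.64
```

A 3×3 square shifted by one pixel in both axes scores 0.44; the same
offset on a 5×5 square already scores 0.64.  Case-level detection metrics
come from per-group counts; for a cohort with 15 small-tumor cases all
detected, 7 hyperintensity-carrying normals all falsely flagged, and 15
plain normals of which 3 are flagged:

```r
tab <- detection_table_from_counts(
  detected     = c(small_tumor = 15, normal_hyperintense = 7, normal_plain = 3),
  not_detected = c(small_tumor = 0,  normal_hyperintense = 0, normal_plain = 12))
detection_metrics(tab)
#> # A tibble: 1 × 3
#>   sensitivity specificity_all specificity_excl_hyper
#>         <dbl>           <dbl>                  <dbl>
#> 1         100            54.5                     80
```

Sensitivity is perfect, overall specificity 54.5%, and 80% once the
hyperintensity confounders are excluded.

See `vignettes/methods.Rmd` for the full account of the models, the
pretext task, the phantom generator and every numerical design choice.

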