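# octametrics

Quantification of en face **OCT angiography** (OCTA) images and paired
comparison of acquisition modes.

OCTA maps retinal blood flow without dye, but the numbers clinicians quote
from it — perfusion density, vessel length density, vessel caliber,
choriocapillaris flow deficits — depend on a fragile image-processing chain
and on acquisition noise. A single scan volume (V1) is speckled; averaging
four registered volumes (V4) improves the signal-to-noise ratio and
measurably shifts every one of those metrics. This package implements the
full measurement chain and the cohort-level agreement statistics needed to
quantify that shift, plus a seeded synthetic-angiogram generator with known
ground truth so the whole pipeline can be validated end to end.

## What it computes

For the superficial (SCP) and deep (DCP) retinal capillary plexuses, from
an 8-bit 304×304 en face image covering 3×3 mm:

1. white top-hat background flattening (disk radius 12 px);
2. dual-path binarization — Hessian (Frangi-type) vesselness followed by
   Huang fuzzy-entropy global thresholding on one copy, median local
   thresholding (radius 15 px) on the other — combined by intersection;
3. Zhang–Suen skeletonization; then

   - **PD** = 100 · |vessel mask| / |frame|  (%)
   - **VLD** = 100 · |skeleton| / |frame|  (%)
   - **VDI** = |vessel mask| / |skeleton|  (pixels; mean caliber), with the
     exact identity VDI ≡ PD / VLD.

For the choriocapillaris (CC): Phansalkar local thresholding
(t = μ(1 + p·e^(−qμ) + k(σ/r − 1)), circular radius-15 window) and
8-connected particle analysis of the signal-void complement, giving the
flow-deficit count, per-deficit areas and total **FD** (% of frame).

For paired V1/V4 cohorts: Shapiro–Wilk-gated paired tests (t or Wilcoxon),
**Lin's concordance correlation coefficient** ρc = ρ·C_b with Fisher-z 95%
CI and the poor/moderate/substantial/perfect bands, and **Bland–Altman**
bias, 95% limits of agreement and bias-significance.

## Worked example

```r
library(octametrics)

cohort  <- generate_cohort(6, seed = 1, image_size = 96)  # 6 eyes, V1 + V4
metrics <- quantify_cohort(cohort)                        # 36 images -> table
report  <- build_agreement_report(metrics)
report
```

```
V1 vs V4 agreement report (6 eyes)

  metric V1 mean (SD) V4 mean (SD) Delta (V1-V4)        p                     CCC category
  SCP PD 44.31 (2.45) 47.63 (2.01)  -3.32 (3.59) 3.13e-02 -0.122 [-0.514, 0.312]     poor
 SCP VLD 30.51 (2.10) 30.02 (2.65)   0.49 (3.80) 4.38e-01 -0.260 [-0.834, 0.585]     poor
 SCP VDI  1.45 (0.02)  1.59 (0.10)  -0.14 (0.10) 1.91e-02 -0.009 [-0.146, 0.129]     poor
  DCP PD 35.77 (0.78) 37.20 (0.90)  -1.43 (0.15) 2.37e-06    0.360 [0.290, 0.426]     poor
 DCP VLD 25.71 (0.65) 23.68 (0.87)   2.03 (0.51) 2.02e-04    0.150 [0.017, 0.278]     poor
 DCP VDI  1.39 (0.01)  1.57 (0.04)  -0.18 (0.04) 6.09e-05    0.003 [-0.009, 0.015]     poor
   CC FD 57.58 (1.09) 52.38 (1.46)   5.20 (0.49) 1.54e-06    0.086 [0.057, 0.115]     poor
```

Each row is one metric; Δ is V1 − V4. Averaging raises perfusion density
and caliber (negative Δ), lowers vessel length density (noise fragments
count as extra "length") and shrinks CC flow deficits — and despite the
systematic shift the two modes agree poorly as *interchangeable* measures
(CCC far below 0.90), which is exactly why acquisition mode must be held
fixed in longitudinal studies. `plot(report)` draws the Bland–Altman panel
per metric.

Lower-level entry points (`binarize_plexus()`, `compute_vascular_metrics()`,
`compute_cc_metrics()`, `phansalkar_threshold()`, `huang_threshold()`,
`skeletonize()`, `concordance_correlation()`, `bland_altman()`) are exported
individually; `vignette("octa-quantification-methods")` documents the model,
every tunable parameter, and the design decisions. A command-line wrapper
lives at `inst/cli/octametrics.R`
(`octametrics.R simulate|quantify|report --config cfg.json`); images are
read and written as 8-bit grayscale TIFF/PNG, tables as CSV, reports as
CSV + JSON.

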