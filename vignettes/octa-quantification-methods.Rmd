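---
title: "Quantifying OCTA en face images: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying OCTA en face images: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octametrics)
```

## The measurement problem

Optical coherence tomography angiography (OCTA) maps retinal blood flow by
decorrelation between repeated scans. The resulting en face images — one per
vascular slab — are quantified through a binarization chain whose output
feeds three standard metrics per retinal plexus and one for the
choriocapillaris (CC):

* **Perfusion density (PD)** — percent of the frame covered by the binary
  vessel mask.
* **Vessel length density (VLD)** — percent of the frame covered by the
  skeleton of that mask, a caliber-independent length measure.
* **Vessel diameter index (VDI)** — vessel area divided by skeleton length,
  i.e. the mean caliber in pixels (about 9.9 µm per pixel at the default
  3 mm / 304 px scale).
* **Flow deficits (FD)** — percent of the CC frame occupied by signal
  voids.

Because VLD's and PD's denominators coincide, `VDI = PD / VLD` is an exact
identity, and the package asserts it on every computed result.

A single-volume acquisition (V1) is noisy; averaging four independently
acquired volumes (V4) suppresses speckle by roughly √4. The package's second
purpose is to quantify how that acquisition choice shifts the metrics, using
paired cohort statistics: a Shapiro–Wilk-gated paired test, Lin's
concordance correlation coefficient (CCC), and Bland–Altman limits of
agreement.

## The binarization chain

SCP/DCP images are processed as:

1. **White top-hat** (disk radius 12 px): subtracts the morphological
   opening, flattening background slower than the disk. 12 px (~118 µm)
   sits just above the largest arteriole caliber we simulate, so vessels
   survive while slab-level background shading is removed.
2. The image is duplicated into two paths:
   * **Path A** — Hessian (Frangi-type) vesselness, maximized over Gaussian
     scales {1, 2, 3, 5} px, followed by Huang fuzzy-entropy global
     thresholding of the vesselness map.
   * **Path B** — median local threshold: foreground where the pixel
     exceeds the median of its 31×31 neighborhood (radius 15, replicated
     edges, offset 0).
3. **Combination** — the intersection (AND) of the two masks. The
   intersection suppresses the single-path failure modes: path B marks
   about half of any textured background (a median is scale-free), while
   path A alone bridges parallel capillaries at coarse scales.

Two vesselness parameters deserve comment, because common defaults fail on
dense plexus meshes. The blobness weight `beta = 0.5` of the classical tube
filter suppresses everything whose local Hessian is not cleanly
one-dimensional; capillary junctions and crossings — which are most of a
plexus at 40–55% area coverage — then score near zero and the recovered
density is biased more than ten points low. We default to `beta = 1`.
Similarly the scale list must reach half the largest expected caliber;
scales capped at 3 px leave 10–12 px arterioles hollow. We default to
{1, 2, 3, 5} px. Both remain arguments of `binarization_params()`.

**Huang threshold.** For each candidate threshold the gray levels are split
at `t`; each level's fuzzy membership is `1/(1 + |g − m_class|/C)` with
`m_class` the class mean and `C` the gray range; the Shannon pair entropy of
the memberships, weighted by the histogram, is minimized. Ties break to the
smallest `t`, candidates are all 8-bit levels with two non-empty classes,
and the implementation is verified against an exhaustive per-pixel
evaluation. Intensities are rounded to integers first (the 8-bit ImageJ
convention); the vesselness map is rescaled to [0, 255] before
thresholding.

**CC flow deficits.** The CC image is binarized with the Phansalkar local
threshold — `t = μ(1 + p e^{−qμ} + k(σ/r − 1))` over a circular radius-15
window with the conventional constants k = 0.25, r = 0.5, p = 2, q = 10 —
and the void mask (complement of flow) is labeled with 8-connected
components, each reported with its area. No minimum-size floor is applied
by default; `phansalkar_params(min_deficit_px = )` enables one for
sensitivity analyses. Note the direction of the `k` term: raising `k`
*lowers* the threshold wherever the local SD is below `r`, so flow pixels
can only be gained there and only lost where the window is busier than `r`.

**Skeletonization.** Zhang–Suen two-subiteration thinning. Parallel
thinning deletes a compact 2×2 blob outright (all four pixels satisfy every
deletion test simultaneously), which would break the
component-count-preservation invariant; any component left without a
survivor is therefore marked by a single pixel. Skeleton "length" is the
pixel count, matching the ImageJ-style VLD the published values imply; a
Euclidean polyline variant (`vessel_length_euclidean()`) is provided. End
erosion is real: thinning a 7×50 bar leaves 43 pixels, not 50, so
area/length slightly overestimates caliber on short segments, while an
image-spanning 7 px tube recovers VDI ≈ 7.4.

## The synthetic cohort

No public OCTA images accompany the study conditions we emulate, so the
package generates phantoms with known ground truth:

* **SCP** — 4 large vessels (caliber 6–12 px) entering from the image
  border plus a random-walk capillary mesh (1–3 px) grown until the vessel
  mask covers 55% of the frame (±20% relative is enforced; the achieved
  fraction is part of the ground truth).
* **DCP** — thin capillaries only (1–3 px, 45% target), drawn as spiral
  paths steered around a central epicenter and terminated at a perifoveal
  inner ring; a naive "walk to the center" rule piles paths into a solid
  disk, which is neither anatomical nor quantifiable.
* **CC** — band-limited bright granular texture with irregular dark blobs
  grown to a 30% void fraction.

Tubes are rendered with anti-aliased coverage and the boolean truth mask is
the canvas thresholded at 0.5, so `true_pd`, `true_vld`, `true_vdi` and
`true_fd` are unambiguous pixel counts. Clean images carry a smooth ±10%
multiplicative field emulating perfusion heterogeneity; perfectly flat
vessel interiors are degenerate for any strict-inequality median threshold
(the local median equals the interior value exactly).

**Noise.** An acquisition is the pixelwise mean of `n_volumes` independent
frames of `pixel·(1+ε) + f`, with ε ~ N(0, σ²) multiplicative speckle and a
small additive floor f ~ N(0, 4²), clipped to [0, 255] and quantized to
8 bits. The default σ = 0.8 corresponds to near-fully-developed speckle
(contrast ratio approaching 1). That choice matters: at mild noise
(σ ≤ 0.45) threshold-level false positives in the background offset vessel
dropout and the V1−V4 perfusion-density difference washes out, while far
above σ = 0.8 fragmentation is so severe that the VLD direction inverts.
σ = 0.8 is the physically sensible regime in which a single volume shows
the vessel discontinuity that averaging repairs, and it was fixed once,
before the validation suite was frozen. A pure additive Gaussian model is
retained for analytic tests (its √n averaging law is checked by Monte
Carlo).

Cohorts jitter each eye's density and caliber targets by ±10% so paired
statistics see realistic between-eye variance. A 28-eye cohort means
168 images (28 × 3 slabs × 2 modes); everything is a pure function of the
master seed.

What the phantoms do *not* model: SSADA decorrelation statistics, motion
or registration artifacts between averaged frames, projection artifacts,
segmentation errors, or the foveal avascular zone. Passing recovery tests
therefore demonstrates that the measurement chain is faithful on images
whose geometry and noise are known — not that it is unbiased on any
particular device's output.

## Agreement statistics

Differences are always `V1 − V4`. The paired test is gated on the
Shapiro–Wilk normality of the differences at α = 0.05 (t-test if normal,
Wilcoxon signed-rank otherwise); all-zero differences return p = 1 with a
degeneracy flag, constant non-zero differences p = 0.

Lin's CCC uses biased (1/n) moment estimators:
ρc = 2s_xy / (s_x² + s_y² + (x̄ − ȳ)²), reported with its factorization
ρc = ρ·C_b (precision × accuracy) and a 95% CI from the Fisher z-transform
with Lin's asymptotic SE. Agreement bands: poor < 0.90, moderate
[0.90, 0.95), substantial [0.95, 0.99], perfect > 0.99 — boundaries
left-closed, 0.99 itself substantial.

Bland–Altman reports bias, 1.96·SD limits of agreement (sample SD), a
Student-t CI for the bias, and flags the bias significant when zero falls
outside that CI. Eyes are paired strictly by `eye_id`; rows may arrive in
any order, and eyes missing one arm are excluded per metric with a logged
count.

## Worked example

A small cohort end to end (96 px frames keep the vignette fast; analyses
use the default 304 px):

```{r example, eval = FALSE}
cohort <- generate_cohort(6, seed = 1, image_size = 96)
metrics <- quantify_cohort(cohort)
report <- build_agreement_report(metrics)
report
plot(report, metrics = c("SCP PD", "CC FD"))
```

## Problem sizes and numerical choices

The validation suite exercises a 28-eye, 304 px cohort (the size of the
cohort whose published summary statistics anchor the reference table in
`reference_metrics()`), 100-image exhaustive-oracle sweeps at 16×16, a
1000-replicate null calibration of the paired test, and a 10⁴-pair
limits-of-agreement coverage check. Degenerate inputs fail loudly and
early: constant images have no Huang threshold, empty skeletons no VDI,
constant arms no CCC. All window operations replicate edges (by index
clamping, so corner windows re-weight edge pixels); disk and circular
windows use the dx² + dy² ≤ r² lattice; ties in the Huang objective break
to the smallest threshold.

## Known limitations

* The binarization chain is one dialect of a family; absolute PD/VLD/VDI
  values are not comparable across chains or devices, which is precisely
  why paired, same-chain comparisons are the package's unit of analysis.
* VDI inherits skeleton end erosion and is biased upward on short stubs.
* The CC Phansalkar step assumes bright-flow/dark-void polarity and no
  pre-filtering of the raw en face slab.
* Phantom realism bounds what green tests prove; see the cohort section.
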