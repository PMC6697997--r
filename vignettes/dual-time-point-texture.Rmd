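---
title: "Dual-time-point PET texture analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-time-point PET texture analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

FDG-avid solitary pulmonary nodules are hard to classify from uptake alone:
granulomatous and tuberculous lesions take up tracer as avidly as tumors, so
SUVmax-based rules produce many false positives in granuloma-endemic
populations, and the early-to-delayed retention index adds little for
FDG-avid lesions. The working hypothesis behind this package is spatial:
inflammatory tissue tends to organize as several spatially separated
high-uptake foci, whereas tumors concentrate uptake into one compact region,
and the contrast between the two architectures sharpens on delayed images as
background activity clears and tumor cells continue to accumulate tracer.
Local gray-tone texture - not the uptake level - is the measurement that
captures this.

`petngtdm` implements that measurement and the statistical analysis around
it: voxel-wise neighborhood gray-tone difference matrix (NGTDM) features on
early and delayed PET volumes, cohort-level inclusion filtering,
benign/malignant group comparison, ROC analysis with a closest-to-corner
operating point, stratified cross-validation, and simulated ordinal reader
scores - plus a synthetic dual-time-point phantom generator so that every
stage is testable without patient data.

## The texture model

### NGTDM on a 2-D patch

A patch of gray levels is first quantized to integer bins. For each eligible
pixel with bin value $i$, let $A$ be the mean bin value of its neighbors
within distance $d$ (the center excluded). The NGTDM accumulates

$$s(i) = \sum_{\text{pixels of level } i} |i - A|,$$

with $p(i)$ the fraction of considered pixels at level $i$, $N_g$ the number
of levels present and $n$ the number of considered pixels. The three features
are

* coarseness $= \left[\varepsilon + \sum_i p(i)\,s(i)\right]^{-1}$ — large
  when local differences are small (big uniform granules);
* contrast $= \left[\frac{1}{N_g(N_g-1)}\sum_i\sum_j p(i)p(j)(i-j)^2\right]
  \cdot \left[\frac{1}{n}\sum_i s(i)\right]$ — gray-level dispersion times
  mean neighborhood difference;
* busyness $= \left[\sum_i p(i)s(i)\right] \big/
  \left[\sum_i\sum_j |i\,p(i) - j\,p(j)|\right]$, sums over levels with
  $p \ne 0$ — high when intensity alternates rapidly between neighboring
  pixels.

Conventions for degenerate inputs: a patch with a single gray level returns
contrast 0 and busyness 0 (the textureless limit must not inject NaN into
lesion averages), and coarseness caps at $1/\varepsilon$.

Two properties worth knowing when interpreting results:

* Coarseness and contrast are invariant when all bins are translated by a
  constant; **busyness is not**, because its denominator weights
  probabilities by the absolute gray level $i$. This is a property of the
  feature's definition, not an implementation artifact.
* The busyness denominator can nearly cancel in quiet regions (two levels
  with $i\,p(i) \approx j\,p(j)$), making per-voxel busyness heavy-tailed on
  very smooth noise-free images. Measurement noise regularizes it; see the
  fragmentation sweep below.

### Voxel-wise scheme

Lesion volumes are quantized with 128 equal-width bins spanning the
intensity range *inside the lesion mask* (the maximum maps to bin 128;
out-of-mask voxels that fall inside extracted sub-volumes are binned with
the same lesion-derived edges and clamped to [1, 128]). Because the edges
are min-max within the lesion, every downstream feature is invariant to a
global affine rescaling $a \cdot \mathrm{SUV} + b$ ($a > 0$) of the volume —
a deliberate property, since dual-time-point comparisons must not be
confounded by global uptake scaling.

Around each lesion voxel a 5×5×5 sub-volume is extracted (cells outside the
image are flagged invalid, never imputed). Each NGTDM feature is computed on
the central 5×5 plane of each of the three orientations (axial, coronal,
sagittal) and averaged over the planes that produced a defined value; the
lesion feature is the mean over lesion voxels with defined features, with
the undefined count reported. Early and delayed volumes are quantized and
processed independently.

Design choices that the underlying description left open, and how they were
resolved:

* **Neighborhood distance** $d = 1$ (8-connected in 2-D): the classical
  default, and the only choice that leaves a 5×5 patch with interior pixels.
* **Pixel eligibility**: default `"strict-interior"` (a pixel enters the
  matrix only when its full $(2d+1)^2$ neighborhood is valid), matching the
  original NGTDM definition; `"all-valid"` (use whatever valid neighbors
  exist) is provided because a 5×5 patch under the strict rule uses only its
  central 9 pixels. Both policies are implemented in the compiled kernel and
  in the brute-force oracle the tests compare against.
* **Plane selection**: "each directional plane" is read as the single
  central plane per orientation (one feature per orientation, then the
  three-way average); an all-slices variant is available via
  `texture_config(planes = "all")`.
* **$N_g$** counts levels present among considered pixels, not the full
  128-bin range, matching the "gray tones present" reading of the contrast
  normalization.
* **$\varepsilon = 10^{-8}$**: far below one bin-difference unit, so it only
  matters for exactly-constant patches; exposed in `texture_config()`.
* **Busyness denominator**: the full ordered double sum over present
  levels. The literature is ambiguous about a factor of two here; the
  convention is applied identically in the implementation and in the
  independent test oracle, and all cohort-level conclusions are invariant
  to it.

## The synthetic cohort

No patient data ships with the package; the generator produces
dual-time-point phantoms whose structure encodes the biological story the
analysis is meant to detect, with one lesion per derived seed so cohorts
are reproducible lesion by lesion.

* **Grid and blur**: 32³ voxels at 4.25 mm isotropic; focus profiles are
  composed analytically with a Gaussian point-spread function of 8 mm FWHM
  (blob of width $\sigma$ rendered at
  $\sigma_\mathrm{eff} = \sqrt{\sigma^2 + \sigma_\mathrm{PSF}^2}$).
* **Malignant lesions**: a single compact blob ($\sigma$ 2.2–3.6 voxels),
  early peak SUV from a truncated normal matching the reported malignant
  cohort statistics (mean 11.22, SD 6.24, truncated at 3 g/ml), delayed
  uptake multiplier 1.10–1.40 (retention).
* **Benign lesions**: 3–6 small foci ($\sigma$ 0.7–1.1 voxels, relative
  amplitudes 0.7–1.0) placed with pairwise separation at least 4.8× the
  larger effective width of the pair — enough, analytically, to pull the
  inter-focus dip below the 50%-of-maximum isocontour, so benign phantoms
  have ≥ 2 connected high-uptake components by construction. Early peak SUV
  from a truncated normal (mean 6.94, SD 3.58, min 3); delayed multiplier
  0.85–1.05 (washout/stable).
* **The delayed-image mechanism is structural, not scalar.** Texture
  features are affine-invariant, so the delayed uptake multiplier alone
  cannot move them. Benign foci sharpen on the delayed image (radii ×0.8)
  and de-cohere (log-normal per-focus amplitude jitter, SD 0.15), emulating
  inflammation resolving into finer structure as background clears;
  malignant blobs keep their shape while their higher peak lowers the
  relative noise level. This is what makes the delayed benign/malignant
  texture gap exceed the early one.
* **Noise**: additive white Gaussian, SD 0.2 SUV on early images and 1.3×
  that on delayed images (tracer decay). White noise is a simplification —
  reconstructed PET noise is spatially correlated — and is the main respect
  in which passing tests do *not* certify behavior on real data, along with
  the idealized spherical-Gaussian lesion geometry and the absence of
  respiratory motion, scatter and reconstruction artifacts.
* **Masks**: thresholded at 25% of the maximum of an extra-smoothed
  envelope rendering, guaranteeing a single practical envelope around
  multifocal lesions; focus radii are enlarged and the lesion re-rendered
  (bounded retries) if a draw would produce fewer than 64 voxels, so every
  generated lesion passes the cohort inclusion filters (volume ≥ 64 voxels,
  early SUVmax ≥ 2.5 g/ml) by construction. The SUVmax filter is applied to
  the early scan — the clinical screening acquisition.

### The fragmentation sweep

`fragmentation_phantom()` isolates the causal mechanism: one blob's
activity split into 1/2/4/8 equal-activity foci of fixed individual size on
symmetric layouts of growing spatial frequency, with the mask fixed to the
400 highest-activity voxels of the noise-free pattern so metabolic volume is
identical across the sweep. The monotone property — busyness non-decreasing,
coarseness non-increasing with fragmentation — is asserted on the
Monte-Carlo expectation over 15 noise replicates. The expectation is the
right object: a single noise draw wobbles a few percent around the trend,
and on *noise-free* renderings per-voxel busyness is dominated by the
denominator cancellations described above (coarseness, whose reciprocal is
exactly the mean weighted neighborhood difference, is monotone in every
construction we examined). The replicate-averaged design was verified
monotone on ten independent base seeds before being frozen.

## The statistical layer

* **ROC**: trapezoidal AUC over all score thresholds, which equals the
  Mann-Whitney statistic with ties counted half (tested against exhaustive
  pair enumeration). The optimal operating point minimizes the Euclidean
  distance to the (0, 1) corner; equidistant candidates break toward higher
  specificity — false positives are the costly error in granuloma-endemic
  settings — then toward the lower threshold. The reported threshold is the
  midpoint of the selected point's equivalence interval, so the same
  training confusion is reproduced while new cases falling inside the
  margin split it. Orientation (`score >= threshold` vs `<=` for
  malignancy) is auto-detected as the direction with AUC ≥ 0.5 unless
  forced: busyness runs *higher* in benign lesions, coarseness higher in
  malignant ones.
* **Wilcoxon rank-sum**: exact by enumeration of all group assignments for
  pooled n ≤ 12, otherwise a normal approximation with tie and continuity
  corrections. The continuity correction is required for the approximation
  to track the exact enumeration within 0.01 at 10 per group (without it
  the deviation reaches ~0.03); the reported z omits the correction, as
  descriptive tables conventionally do. Fully tied data return p = 1.
* **Cross-validation**: stratified 11-fold by default. Within each class,
  fold counts are as equal as possible and remainders go to the folds with
  the smallest running totals, so 116 lesions give six folds of 11 and five
  of 10 while every fold retains benign cases (with 35 benign among 116,
  unstratified folds can easily lose a class; an unstratified mode is
  kept). Thresholds are fitted on each training partition and applied
  untouched to the held-out fold; fold metrics are averaged arithmetically.
  Both reporting modes — full-cohort ROC and cross-validated fold averages —
  are emitted, since either may be wanted.
* **Reader scores**: latent score = standardized feature + Gaussian noise,
  cut into 1–5 by the fixed 20/40/60/80% quantiles of the latent
  distribution. Lower noise models readers who reference the texture
  values; the correlation gap between the two noise settings (defaults 0.8
  and 1.3) exercises the correlation analysis, not a model of human
  perception.

## Problem sizes and numerical notes

The default study runs 116 lesions × 2 time points on 32³ grids
(≈ 400–1200 mask voxels per lesion); feature extraction for a full cohort
takes a few seconds with the compiled kernel, and the complete acceptance
analysis (cohort generation, extraction, ROC, CV, correlations) runs in
well under a minute. Tests exercise the same cohort size over three seeds;
oracle-equivalence sweeps use 1000 random patches per run at relative
tolerance 1e-10. Volumes are written as float64 NIfTI so disk round trips
preserve features to better than 1e-9. All randomness descends from
explicit seeds through a fixed RNG kind; identical configurations produce
byte-identical report bundles.

## Known limitations

* The phantom family is idealized (Gaussian foci, white noise, no motion,
  no attenuation or reconstruction artifacts); conclusions about real
  scanners require real data.
* Busyness should be compared only between images quantized the same way:
  it is not invariant to gray-level translation, and its denominator makes
  it ill-conditioned on nearly noise-free smooth regions.
* Only the three NGTDM features are implemented (no complexity/strength, no
  GLCM/GLRLM families, no 3-D 26-neighbor NGTDM); segmentation,
  registration between time points and partial-volume correction are out of
  scope — masks are inputs.
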