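---
title: "Multi-mode spectral assessment of fish-fillet freshness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-mode spectral assessment of fish-fillet freshness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freshspec)
```

## The problem

Post-mortem decay of fish muscle proceeds on a scale of days and is hard to
judge on fillets, where the usual whole-fish cues (eyes, gills, odour) are
gone. Two optical phenomena track that decay. First, the fluorescence
emission spectrum under 365 nm excitation changes shape: a primary peak P1
stays fixed near 452.6 nm while a subsidiary peak P2 moves closer to it and
gains relative intensity, so the separation Δλ = λ(P2) − λ(P1) shrinks and
the height ratio P1/P2 grows with age. Second, diffuse reflectance in the
VisNIR (419–1007 nm) and SWIR (842–2532 nm) windows drifts as water
binding, pigment and protein states change. In parallel, the nucleotide
pool degrades along IMP → inosine → hypoxanthine, which grounds the
spectral story in the standard wet-chemistry freshness indices

$$K = \frac{\mathrm{Ino} + \mathrm{Hx}}{\mathrm{IMP} + \mathrm{Ino} +
\mathrm{Hx}}, \qquad
H = \frac{\mathrm{Hx}}{\mathrm{IMP} + \mathrm{Ino} + \mathrm{Hx}}.$$

Printed variants of the simplified K-value occasionally replace these sums
with products — a typesetting artifact that would not yield a bounded,
monotone index — so the package deliberately implements the standard
additive form above. Both indices run from 0 (all IMP) to 1 (all
hypoxanthine) and are non-decreasing along the kinetic flow, which the test
suite verifies against a Runge–Kutta integration of the two-step pathway.

`freshspec` turns these observations into a classification pipeline:
hypercubes → clean voxel spectra → aging features and per-mode day
classifiers → decision-level fusion → graded accuracy reports.

## The synthetic study generator

No public spectra exist for this problem, so the package's first module
generates data with exactly the statistical structure the analysis assumes;
every downstream stage is tested against it.

* **Fluorescence.** A shallow linear baseline plus two Gaussians: P1 at
  452.6 nm (FWHM ≈ 40 nm) and P2 at P1 + Δλ(day), with
  Δλ(day) = Δλ(1) − s·(day − 1)/10. The defaults Δλ(1) = 85 nm and total
  shrink s = 20 nm mirror the strongest regional trend reported for salmon
  tail sections; the P1/P2 ratio grows linearly from 0.8 at day 1 by
  0.06/day. P2's FWHM is drawn once per model from 103.9–115.9 nm. A small
  Gaussian bump at the short-wavelength edge emulates incomplete rejection
  of the excitation band by the optical filter. Because the generator's
  functional form equals the deconvolution model, the peak extractor is
  exactly identifiable on noise-free data — a deliberate design choice that
  turns parameter recovery into a sharp test.
* **Reflectance.** A smooth species-specific base profile (constant plus a
  few broad Gaussian bumps, drawn deterministically from the species/seed
  pair) modulated by day-weighted drift components, linear plus a mild
  quadratic term so each day has a distinct spectral shape. Magnitudes of
  reflectance aging drift are free parameters of the generator: the default
  (≈12% full-course band-dependent drift against 1% relative noise) was
  chosen once as a realistic chemometric contrast and is not calibrated to
  any particular fish.
* **Geometry and artifacts.** Full-size cubes are 500×280 pixels with
  60/125 bands (FL/VisNIR) and 384×350 with 287 bands (SWIR). The fillet is
  an elliptical foreground over a dark connected background, split into
  head/tail × top/bottom regions with multiplicative gradients; saturated
  pixels are planted as whole 10×10 tiles clipped at the detector ceiling,
  so the voxel-rejection rule can be checked against the exact planted set.
  Reflectance cubes carry per-line-pixel white and dark reference frames
  and store raw counts as `reflectance · (white − dark) + dark`.
* **Study design.** Measurement days default to {1, 3, 5, 7, 9, 11}, with
  a switch to drop day 5 (mirroring a saturation-spoiled acquisition in the
  motivating experiment). Noise is additive, band-independent and scaled to
  the clean signal's maximum (1% by default); a per-voxel intensity jitter
  (SD 1.5%) adds spatial heterogeneity. All randomness flows from a single
  seed; identical seeds give bit-identical datasets.

What the generator does **not** emulate: radiometric detail (quantum
efficiency, stray light), fluorophore chemistry, instrument-to-instrument
geometric registration, and spectral covariance structure of real muscle.
Passing tests therefore demonstrate that the algorithms are implemented
correctly and recover planted structure under realistic noise — not that
real fillets of any species will separate this cleanly.

## Preprocessing

The chain is fixed and logged: calibrate → exposure-scale → mask →
voxelize → flag outliers → (optional pretreatment).

* Reflectance calibration is the element-wise flat-field formula
  `(raw − dark)/(white − dark)`; a non-positive `white − dark` anywhere is
  an error naming the offending band.
* Exposure scaling multiplies by `reference_ms / exposure_ms`, assuming the
  detector is linear in exposure time (the assumption behind scaling
  acquisitions shortened from 300 to 50 ms to a common scale).
* The mask thresholds a summary image (across-band mean by default) at a
  relative level between robust 5%/90% quantile anchors — robust so that a
  few saturated pixels cannot stretch the contrast range — and keeps the
  largest connected component (`EBImage::bwlabel`).
* Voxelization averages complete 10×10 tiles at least half inside the mask;
  incomplete or mostly-outside tiles are dropped so every voxel has
  comparable support.
* The outlier rule recomputes, per wavelength band, the mean and SD over
  all in-mask pixels of the cube, and excludes a voxel when at **any** band
  strictly more than 10% of its member pixels deviate by more than 2 SD.
  The boundary is deliberately strict (> 10%, not ≥): a voxel with exactly
  10% outliers is kept. Statistics are computed per cube (per acquisition),
  not pooled across days — the per-acquisition reading of "over the entire
  fillet" — and the operation is idempotent.
* SNV centres each spectrum to mean 0, SD 1 (sample SD); Savitzky–Golay
  smoothing (`signal::sgolayfilt`) reproduces polynomials up to its order
  exactly. Classification consumes calibrated spectra without SNV by
  default; SNV is a switch.

## Chemometrics

**PCA.** With pretreatment on, spectra are SNV-scaled and the decomposition
uses the correlation matrix, so the eigenvalue > 1 retention criterion is
meaningful; eigenvalue fractions λᵢ/Σλ are reported and sum to one.
Component signs are fixed (largest-magnitude loading positive) to make
results reproducible across linear-algebra backends. The scree rule is
implemented as the index of the largest second difference of the
eigenvalue sequence — the formalisation of the visual elbow.

**SOM + HCA.** The self-organizing map is a rectangular-grid batch
implementation (5×5 default, configurable): codebooks initialise from a
seeded data sample; each epoch assigns every spectrum to its nearest
codebook under the Euclidean distance D = √Σ(aᵢ−bᵢ)² and recomputes
codebooks as Gaussian-neighbourhood-weighted means with a linearly decaying
radius. Batch updates make training deterministic per seed. Spectral
classes come from Ward-linkage hierarchical clustering of codebook vectors,
four classes by default (the two-peak / major-shoulder / minor-shoulder /
single-peak archetypes). Rectangular topology and Ward linkage were chosen
for simple distance bookkeeping and compact classes; both are arguments.
No automatic exclusion of anomalous spectra is performed — an analyst
decision the package declines to automate.

**Peak deconvolution.** A linear baseline is estimated from the
low-intensity quartile, subtracted for peak identification, then refined
jointly in a bounded Levenberg–Marquardt fit (`minpack.lm::nlsLM`) of two
Gaussians. The second component is sought as another significant local
maximum at least 15 nm from the global one on either side (P2 can exceed P1
in height early in the course, so the search must be two-sided); failing
that, a second concave dip of the second derivative (curvature test) marks
an unseparated shoulder. Only when both tests fail is the peak declared
unresolved: the last inflexion point beyond the fitted centre is reported
with an ascribed `delta_lambda_error` of half the fitted Gaussian SD plus
one band spacing. Three perturbed restarts precede failure. P1 is the
shorter-wavelength component. Numerical behaviour, verified in the suite:
centres within 0.5 nm on noise-free two-peak input, median |Δλ̂ − Δλ| under
one band spacing (≈1 nm) at signal-to-noise 50, P1 within 452.6 ± 3 nm on
the default generator.

**Day matching.** A calibration curve maps days to a feature (Δλ or ratio)
measured on a calibration fillet; a query value is assigned the day with
the nearest feature value, ties resolved toward the earlier day — the
conservative freshness claim — and out-of-range values clamped to the
endpoint days. On a synthetic calibration/validation pair at 0.5% noise the
prediction stays within ±1 day. The hit quality index χ = Σ|xᵢ − yᵢ|
provides the complementary whole-spectrum goodness-of-fit ranking (lower is
better; symmetric, non-negative, zero iff identical).

## Classification and fusion

Splits are stratified by day (80/20 default). Eight base classifiers run
with their conventional defaults, pinned in one place so library upgrades
cannot silently change results; the single deliberate exception is
multinomial logistic regression at 1000 iterations. The stacked ensemble
fits LR, RF and KNN, appends their predicted day labels — as labels, not
probabilities — to the original band matrix, and trains an LDA meta-model
on the augmented matrix (width = bands + 3). Appending to the original
features rather than replacing them is the load-bearing choice: the
predictions-only variant measurably underperforms, and the suite asserts
the direction of that comparison. Columns with zero within-class variance
(a base model reproducing its training labels exactly, common on clean
synthetic data) are dropped from the meta-fit since they carry no
discriminant information and would make the within-class scatter singular.
When the stacker is itself cross-validated, base models are refit within
every fold; test rows never touch any fit, which a serialization-identity
leakage test enforces. KNN vote ties are broken under a model-local seed so
predictions are reproducible.

Fusion is decision-level only: per test voxel, the three modes vote; a
label with two votes wins, and a three-way disagreement falls back to the
SWIR prediction (the mode with the consistently highest single-mode
accuracy). Feature-level concatenation across modes is an explicit
non-goal. Because the two real instruments do not image the same physical
voxels, voxel-level index alignment is only exact on synthetic data; the
report therefore also aggregates to fillet-day verdicts (majority over each
true day's voxels), which is the level at which fused accuracies are
meaningful for real acquisitions. The repeated-measurement booster is the
binomial majority probability Σ_{k>n/2} C(n,k) pᵏ(1−p)ⁿ⁻ᵏ; at p = 0.95,
n = 3 it gives 0.99275.

Accuracies are reported exact, within ±1 day (equal to exact on an
alternate-day class grid, where the minimum gap is two days), and collapsed
to three grades (fresh ≤ day 5, fairly fresh ≤ day 7, spoilt) and two
grades (fresh ≤ day 5, spoilt). Collapsing is done on both axes of the
confusion matrix; merging can only convert errors to hits, so grouped
accuracy never falls below exact accuracy.

## Problem sizes and degenerate inputs

The test suite and the acceptance script run studies of 20–120 voxels per
fillet-day (100–600 voxels per mode) and reduced 120×100 cubes for the
masking/outlier checks, alongside single full-size cubes for geometry and
format round-trips; these sizes were chosen so the whole suite exercises
every path in well under a minute while keeping per-class training counts
above the QDA dimensionality requirement. Degenerate inputs are errors with
named causes: constant spectra under SNV, even smoothing windows, empty day
lists, classes with a single row, all-zero catabolite profiles, empty
foregrounds, non-positive white−dark references, saturation fractions ≥ 1
and mismatched fusion lengths. Equal catabolite rate constants use the
analytic limiting form rather than the generic two-exponential solution.

## Known limitations

The generator's aging trends are linear in day and its noise is
band-independent — real spectra drift nonlinearly and correlate across
bands, so reported synthetic accuracies are upper bounds, not forecasts.
Reflectance drift magnitudes are uncalibrated free parameters. The ENVI
reader covers the float32/float64 little-endian subset the package writes.
Cross-instrument geometric registration is out of scope; fusion of real
data should be read at the fillet-day level only.
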