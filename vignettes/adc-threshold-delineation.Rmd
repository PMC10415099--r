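---
title: "ADC-threshold delineation of acute stroke lesions: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ADC-threshold delineation of acute stroke lesions: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcstroke)
```

## The problem

In acute ischemic stroke, the diffusion-weighted imaging (DWI) lesion is the
working estimate of irreversibly injured tissue. Commercial segmentation
software delineates it by thresholding the apparent diffusion coefficient
(ADC) map — most commonly at ADC ≤ 620 × 10⁻⁶ mm²/s — but a fixed threshold
interacts with lesion size, lesion ADC and parenchymal ADC in ways that are
rarely quantified. `adcstroke` implements a fully automated
threshold-based delineation pipeline together with the complete evaluation
battery needed to characterise such thresholds: per-subject and pooled
voxelwise ROC analysis with Youden-index threshold selection, Dice overlap,
Bland–Altman volumetric agreement, and standardized-coefficient regression
of performance on per-subject factors. Because suitable patient cohorts are
not publicly available, the package ships a physics-grounded synthetic DWI
phantom generator so every part of the pipeline can be exercised,
validated and stress-tested end to end.

## The delineation pipeline

The input is a co-registered, brain-extracted triplet of 3-D volumes on one
grid — b0, trace (b = 1000 s/mm²) and the ADC map in 10⁻⁶ mm²/s — plus a
brain mask. The pipeline is:

1. **Ratio image** — trace / ADC. Acute infarcts are trace-hyperintense
   and ADC-hypointense, so the ratio amplifies lesion contrast
   multiplicatively. Voxels with ADC ≤ 0 and out-of-brain voxels are set
   to 0.
2. **Per-slice normalization** — each axial slice is divided by the mean
   of its in-brain voxels, making intensities comparable across subjects
   and along the head–foot axis.
3. **Gaussian smoothing** — isotropic, FWHM 5 voxels by default.
4. **Contralateral subtraction** — `max(0, img − flip(img))` about the
   mid-sagittal plane. Symmetric structure (normal anatomy, symmetric
   artifacts, CSF) cancels; unilateral hyperintensity survives.
5. **Intensity threshold and dilation** — voxels ≥ 0.75 (inclusive) in the
   processed image, then one pass of 6-connected binary dilation,
   intersected with the brain mask. This is the *primary mask*.
6. **ADC band gate** — keep primary-mask voxels with
   200 ≤ ADC ≤ 620 × 10⁻⁶ mm²/s (both ends inclusive).
7. **Trace-percentile cleanup** — remove remaining voxels whose trace
   intensity lies strictly below the 95th percentile of the parenchymal
   trace distribution; scattered ADC-dark but trace-dark voxels (chronic
   lesions, partial-volume CSF) are discarded.

Every stage logs its surviving voxel count; the final mask may legitimately
be empty (small or high-ADC lesions can fail every gate, and a symmetric,
lesion-free brain must produce an empty mask).

### Tunables

| parameter | default | units | why |
|---|---|---|---|
| `smoothing_fwhm_vox` | 5 | voxels | matches the kernel width the pipeline was designed around |
| `intensity_threshold` | 0.75 | normalized intensity | the published operating point; exposed, not re-derived |
| `dilation_iterations` | 1 | passes | recovers the smoothing-eroded lesion rim |
| `adc_lower`, `adc_upper` | 200, 620 | 10⁻⁶ mm²/s | the fixed band used by commercial delineation software |
| `trace_percentile` | 95 | percent | scattered-voxel cleanup level |
| `percentile_population` | `"parenchyma"` | — | see below |
| `csf_adc_cutoff` | 2000 | 10⁻⁶ mm²/s | CSF exclusion rule |
| `mirror_axis` | 1 | axis index | left–right axis of the registered grid |
| `slice_axis` | 3 | axis index | inferior–superior (axial slices) |

## Numerical and interpretive choices

Several steps of the published description admit more than one reading;
the package fixes each one explicitly and keeps it configurable where the
intent cannot be recovered:

* **"5 voxel Gaussian kernel"** is read as FWHM = 5 voxels
  (σ = 5/2.3548 ≈ 2.12). The sampled kernel extends to 6σ and is
  normalized to unit sum, so truncation error is ~10⁻⁹ and the Gaussian
  semigroup property (smooth twice with σ ≈ smooth once with σ√2) holds to
  10⁻⁶ on interior voxels — which the tests assert. Boundary handling is
  constant-zero.
* **"Partial dilatation"** is implemented as N passes (default 1) of
  6-connected (face-adjacent) binary dilation, then intersection with the
  brain mask — "partial" read as "constrained to the brain".
* **The 95th-percentile reference population** is the brain-parenchyma
  trace distribution, not the candidate mask: a mask-internal percentile
  would by construction delete 95 % of any lesion. The alternative reading
  is available as `percentile_population = "mask"`.
* **Percentile convention** is linear interpolation between order
  statistics (R's type 7): the 95th percentile of 1…100 is 95.05.
* **Comparisons** are inclusive: intensity ≥ 0.75, ADC band closed on both
  ends, trace cleanup removes strictly-below-cutoff voxels.
* **Contralateral subtraction clips negatives at zero**: only ipsilateral
  hyperintensity is meaningful, and clipping makes the
  symmetric-input ⇒ empty-mask null exact.
* **Slice means are brain-only.** Slices with no in-brain voxels (or a
  non-positive mean) are left unchanged.
* **ADC units** are auto-detected on load: if the 99th percentile of
  positive voxels is below 10, the map is taken to be in mm²/s and
  rescaled by 10⁶. The two dialects differ by six orders of magnitude, so
  any cutoff between ~1 and ~100 is safe. NaN voxels (typical along
  brain-extraction borders) are replaced by 0 and counted in a message.
* **Tissue segmentation** is replaced by an ADC rule: parenchyma = brain
  voxels with ADC < 2000 × 10⁻⁶ mm²/s. Free water sits near 3000 and
  parenchyma well below 2000, so the rule separates the compartments
  without a tissue-segmentation dependency; registration and brain
  extraction themselves are out of scope and assumed done.

## ROC threshold discovery

The classifier is "ADC ≤ t is infarct". For each subject the sweep counts
TP/FP/FN/TN at every threshold of a shared grid against the reference
lesion, with the negative class equal to the search region minus the
truth — whole-brain parenchyma by default, or a lesion-centred region made
by 6-connected dilation of the truth mask (default 3 passes, which
excludes roughly 96–99 % of parenchyma for mid-sized phantom lesions; the
excluded fraction is attached to the region). Choices:

* **Grid**: integers 0…1500 × 10⁻⁶ mm²/s — thresholds in this field are
  conventionally reported as integers, and 1500 covers the full
  parenchymal range.
* **Tie-break**: equal Youden resolves to the *lowest* threshold. With
  perfectly separated classes the optimum therefore sits at the left edge
  of the separation gap.
* **AUC**: trapezoidal rule over (1 − specificity, sensitivity) with
  endpoints (0,0) and (1,1) appended.
* **Pooling** sums the per-threshold count tables across subjects before
  recomputing rates, answering "what single generalized threshold works
  best for the cohort". Pooling can never beat the mean of per-subject
  optima — an inequality the tests assert on every cohort.

Under the phantom's Gaussian compartment model (lesion ADC ~ N(μ_L, σ),
parenchyma ~ N(μ_P, σ)), the Youden-optimal threshold is the
equal-density point of the two distributions — the midpoint when the
spreads are equal. The default compartments (500 ± 60 vs 850 ± 60) put it
at 675, and the acceptance suite checks the sweep recovers it.

## Agreement and regression battery

* **Dice** 2TP/(2TP+FP+FN). Two empty masks are defined as Dice 1
  (perfect agreement on absence) with a warning; a missed nonempty lesion
  is Dice 0 and needs no convention.
* **Bland–Altman** on paired volumes, oriented reference-minus-automated;
  bias = mean difference, limits = bias ± 1.96 sample sd (n − 1). The
  regression and Pearson correlation treat the reference method as the
  x-axis, following the one-method-as-reference variant rather than the
  classic pair-mean axis.
* **Standardized regression**: response and predictors are z-scored
  before ordinary least squares, so coefficients are standardized β with
  95 % Wald intervals and two-sided t-tests, no multiplicity correction.
  Incomplete cases are dropped and counted. Collinear predictors (design
  condition number > 10⁸) raise an error naming the worst pair.

## The phantom: what it emulates, and what it does not

Each case is a mirror-symmetric ellipsoidal brain (2 mm isovoxel by
default, 64×76×52) with two symmetric ventricle-like CSF blobs and one
ellipsoidal lesion placed strictly inside one hemisphere, clear of the
midline and the ventricles. Voxelwise ADC is drawn per compartment —
lesion 500 ± 60, parenchyma 850 ± 60, CSF 3000 × 10⁻⁶ mm²/s — clipped at
zero. The defaults put the lesion between the regimes observed for
automated and manual delineations of acute lesions, with parenchyma and
free-water values in their normal adult ranges; the true within-lesion ADC
distribution shape is unknown, so the normal model is a configuration
choice, not a claim. b0 is a constant S₀ = 1000 inside the brain, and the
trace follows the mono-exponential decay law of the spin-echo EPI
acquisition,

  trace = b0 · exp(−b · ADC · 10⁻⁶),  b = 1000 s/mm²,

so at ADC = ln2/b ≈ 693.1 × 10⁻⁶ mm²/s the signal halves exactly.
Additive Gaussian noise (sd 20, i.e. 2 % of S₀ — a typical DWI
signal-to-noise regime) is applied to b0 and trace and clipped at zero.
The background ADC field is drawn on one hemisphere and mirrored, so a
noise-free case is *exactly* symmetric apart from the lesion: the
mirror-subtraction null (symmetric input ⇒ empty mask) can be asserted
exactly rather than statistically. The mirror plane falls exactly between
the two central voxel columns of the left–right axis, which is therefore
required to be even.

Cohorts draw per-case truth volumes log-uniformly over a target range
(default 0.2–20 mL, solved to sphere radii, so realised volumes match the
target up to surface quantization), jitter the per-case lesion and
parenchyma ADC means (sd 30) to create between-subject variability, and
derive per-case seeds deterministically from one master seed; identical
spec and seed reproduce every voxel bit-for-bit.

The phantom deliberately omits realistic anatomy: no gyral texture,
partial-volume effects, bias fields, Rician noise floor, susceptibility
artifacts or perfusion. Passing tests therefore demonstrate the
*algorithmic* correctness of the pipeline and the statistical behaviour
of thresholds under a controlled contrast model — not clinical
performance on patient data, where registration error, rater variability
and pathology heterogeneity dominate.

## Problem sizes and experiment design

The validation suite runs cohorts of 20 phantoms at the 64×76×52 default
grid: mid-sized (5–20 mL) high-contrast cohorts for segmentation accuracy,
sub-millilitre (0.1–0.5 mL) cohorts for the small-lesion failure mode,
2–20 mL cohorts for threshold recovery, and 10 symmetric lesion-free
cases for the mirror null. Oracle checks (exhaustive voxel counting for
Dice and ROC, hand-enumerated worked examples, closed-form Bland–Altman)
run on 4³–8³ lattices where brute force is exact. The same cohort design,
at the full 0.2–20 mL range with between-subject jitter, drives
`scripts/acceptance.R`.

Two behaviours of the defaults are worth knowing. First, smoothing at
FWHM 5 attenuates small blobs: a sub-millilitre lesion (radius ≲ 2.5
voxels) rarely survives the 0.75 threshold, so tiny lesions are missed
entirely — the small-lesion failure mode is real and by design
reproducible. Second, between-subject ADC jitter can shrink the
lesion–parenchyma contrast (e.g. lesion 540 vs parenchyma 800), and Dice
degrades accordingly; this dependence of performance on lesion ADC and
volume is exactly what the standardized regressions measure.

## Known limitations

* Registration, brain extraction and any resampling are assumed done;
  all volumes in one analysis must share a grid exactly.
* The mirror plane is the array flip along the configured axis — correct
  for template-registered or phantom data only.
* ROC confidence intervals, curve smoothing and threshold
  cross-validation are out of scope.
* The both-empty Dice convention (1.0) matters only for lesion-free
  inputs; cohort statistics here always have nonempty truth.
* The CLI's config file is YAML, mirroring the constructor arguments
  field-for-field.
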