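# adcstroke

Automated delineation of acute ischemic stroke lesions on diffusion MRI by
ADC thresholding, and the statistical machinery to characterise how well
such thresholds work.

## What it does, and for whom

In acute stroke imaging the DWI lesion stands in for the ischemic core,
and most commercial tools delineate it with a fixed apparent diffusion
coefficient (ADC) threshold, typically ADC ≤ 620 × 10⁻⁶ mm²/s. This
package is for stroke-imaging researchers who want to run such a pipeline
and — more importantly — interrogate it: find each subject's best possible
threshold, ask whether one generalized threshold exists, and quantify
which patient factors drive performance.

The package provides:

* a **segmentation pipeline** operating on co-registered, brain-extracted
  b0 / trace (b = 1000 s/mm²) / ADC NIfTI volumes: trace/ADC ratio image →
  per-slice normalization → Gaussian smoothing (FWHM 5 voxels) →
  contralateral mirror subtraction → intensity threshold 0.75 with binary
  dilation → ADC band gate 200–620 × 10⁻⁶ mm²/s → trace 95th-percentile
  cleanup;
* **voxelwise ROC analysis** of the classifier "ADC ≤ t is infarct"
  against a reference lesion over the whole-brain parenchyma or a
  lesion-centred dilated region, per subject and pooled, with the Youden
  index J = sensitivity + specificity − 1 selecting the operating
  threshold and trapezoidal AUC;
* **evaluation statistics**: Dice overlap 2TP/(2TP+FP+FN), Bland–Altman
  volumetric agreement (bias ± 1.96 SD limits), Pearson correlation, and
  linear regression with standardized coefficients;
* a seeded **synthetic DWI phantom** generator whose trace signal follows
  the mono-exponential decay law `trace = b0·exp(−b·ADC·10⁻⁶)`, with
  parenchyma/CSF/lesion compartments, mirror-symmetric background and
  exact ground-truth lesion masks — so the entire pipeline is testable
  without patient data;
* a command-line front end (`exec/adcstroke`) with `simulate`,
  `delineate`, `roc`, `roc-pool`, `evaluate`, `cohort-stats` and
  `run-all` subcommands sharing one YAML config.

## Worked example

Generate a synthetic case with a ~9 mL lesion, delineate it, and find the
subject's optimal ADC threshold:

```r
library(adcstroke)

spec <- PhantomSpec(seed = 7, lesion_radii_vox = c(6.5, 6.5, 6.5))
case <- generateCase(spec)

res <- delineate(case@b0, case@trace, case@adc, case@brain_mask)
res
#> SegmentationResult
#>   lesion: BinaryMask 64x76x52, spacing 2x2x2 mm: 1060 voxels (8.480 mL)
#>   stage log (surviving voxels):
#>     threshold          734
#>     primary_mask       1102
#>     adc_gate           1060
#>     trace_cleanup      1060

diceCoefficient(res@lesion_mask, case@truth_lesion)
#> [1] 0.96

par <- parenchymaMask(case@adc, case@brain_mask)
rocSweep(case@adc, case@truth_lesion, par)
#> ROCResult: 1501 thresholds, 1148 positive / 76448 negative voxels
#>   optimal ADC <= 677: J = 0.996 (sens 0.998, spec 0.998), AUC = 1.000
```

Reading the output: the intensity threshold finds 734 suprathreshold
voxels, dilation grows the primary mask to 1102, the ADC band gate trims
it to 1060, and the percentile cleanup removes nothing further — an
8.48 mL automated lesion overlapping the truth at Dice 0.96. The
subject's own ROC sweep puts the optimal threshold at 677 × 10⁻⁶ mm²/s,
the equal-density point of the phantom's lesion (500 ± 60) and parenchyma
(850 ± 60) ADC distributions — noticeably above the fixed 620 gate, which
is exactly the kind of subject-level discrepancy the package is built to
measure.

The same run from the shell:

```sh
exec/adcstroke simulate --out cohort/ --n 20 --seed 7
exec/adcstroke delineate --b0 cohort/case_001/b0.nii.gz \
  --trace cohort/case_001/trace.nii.gz --adc cohort/case_001/adc.nii.gz \
  --brain-mask cohort/case_001/brain.nii.gz --out case_001_lesion.nii.gz
exec/adcstroke run-all --out report/ --n 20 --seed 7
```

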