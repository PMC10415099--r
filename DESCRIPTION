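Package: adcstroke
Title: ADC-Threshold Delineation and Evaluation of Acute Ischemic Stroke
    Lesions on Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automated delineation of acute ischemic stroke lesions
    on diffusion-weighted MRI using apparent diffusion coefficient (ADC)
    thresholding, together with the complete evaluation battery used to
    characterise such thresholds: voxelwise ROC analysis with Youden-index
    threshold selection (per subject and pooled), Dice overlap,
    Bland-Altman volumetric agreement, and standardized-coefficient linear
    regression of performance on patient factors. Includes a seeded,
    physics-grounded synthetic DWI phantom generator (mono-exponential
    diffusion decay, symmetric brain with CSF and lesion compartments) so
    the whole pipeline can be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
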