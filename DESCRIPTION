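Package: adcvar
Title: Acquisition-Parameter Variability and Apparent Diffusion Coefficient Estimation in Multicenter DWI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how diffusion-weighted MRI (DWI) acquisition parameters affect
    apparent diffusion coefficient (ADC) estimates in multicenter tumor cohorts. Provides a
    calibrated synthetic multicenter cohort generator (bi-exponential IVIM-style signal model,
    Rician noise, tumor/necrotic/muscle masks), voxelwise mono-exponential log-linear ADC
    fitting, ROI median summaries with exclusion regions and a scan inclusion flow,
    coefficient-of-variation analysis of acquisition parameters overall and within centers,
    median-split Mann-Whitney and regression comparisons, and a b-value subset sensitivity
    analysis: ADC over all b-value combinations containing b=0, grouped by highest b-value,
    with the percent-change-per-100 s/mm2 slope and a four-combination longitudinal-change
    analysis with propagated uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
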