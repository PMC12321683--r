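# adcvar

Tools for studying how diffusion-weighted MRI (DWI) acquisition parameters
affect apparent diffusion coefficient (ADC) estimates in multicenter tumor
cohorts — aimed at quantitative-imaging researchers who need to know whether
protocol heterogeneity (echo time, voxel size, b-value schemes) can masquerade
as, or mask, a biological treatment-response signal.

Real multicenter patient DWI is rarely shareable, so the package is driven by
a calibrated synthetic cohort generator: every analysis stage is exercised,
tested and reproduced on simulated data whose summary statistics match a
published multicenter pediatric sarcoma cohort (114 patients, 22 centers,
195 scans).

## The model

ADC is estimated voxelwise by the mono-exponential log-linear fit: for
signals S(b) at b-values b (s/mm²),

    ln S(b) = ln S(0) − b · ADC · 10⁻³,

solved by ordinary least squares on the normal equations; ADC is reported in
µm²/ms. With two b-values this reduces to ADC = ln(S(b₀)/S(b₁))/(b₁−b₀)·10³.

The synthetic signal generator uses a two-compartment (IVIM-style)
bi-exponential decay,

    S(b) = S₀ [ f e^(−b·Dp·10⁻³) + (1−f) e^(−b·Dt·10⁻³) ],

with perfusion fraction f = 0.065 and pseudo-diffusion Dp = 20 µm²/ms for
tumor tissue (f = 0 for muscle). The fast compartment decays away at low b,
which makes the fitted mono-exponential ADC decrease as the highest b-value
in the fit increases — on average 2.8% per 100 s/mm² under the default
calibration. Per-patient tissue diffusivity Dt is solved exactly so that the
two-point ADC at b = 1000 s/mm² equals that patient's target ADC; targets
are drawn from the cohort marginals (tumor 1.09 (0.30) µm²/ms at diagnosis,
1.58 (0.38) at response; muscle 1.20 (0.14) and 1.24 (0.16)). Volumes carry
Rician (magnitude-image) noise.

Downstream analyses: ROI medians with necrotic/cystic exclusion regions
removed; a scan inclusion flow (no measurable tumor → poor quality → no DWI
→ outside field of view); coefficients of variation of five acquisition
parameters overall and within centers; median-split Mann–Whitney tests with
Bonferroni correction and per-parameter regressions; and the b-value subset
sensitivity analysis — ADC over *all* b-value combinations containing b = 0,
grouped by highest b-value, with the percent-per-100 slope and the
four-combination longitudinal-change analysis with propagated uncertainty.

## Worked example

```r
library(adcvar)

coh  <- generateCohort(defaultCohortConfig(), seed = 42)   # 195 scans, ~3 s
flow <- applyInclusionFlow(coh$manifest)
sm   <- roiSummaries(coh$scans, flow$manifest)             # fit + ROI medians
summarizeCohort(sm)
#>   region timepoint   n mean_adc sd_adc min_adc max_adc
#> 1 muscle diagnosis  16     1.17  0.163   0.977    1.59
#> 2 muscle  response  16     1.29  0.172   1.014    1.61
#> 3  tumor diagnosis 112     1.08  0.308   0.332    1.84
#> 4  tumor  response  83     1.55  0.342   0.571    2.22
```

The tumor mean rises from 1.08 to 1.55 µm²/ms between diagnosis and
response while muscle stays flat — the paired signed-rank test gives
p = 8.3e-13 for tumor and p = 0.051 for muscle. Acquisition-parameter
variability mirrors a real multicenter cohort:

```r
variabilityTable(flow$manifest)[, 1:3]
#>            parameter cv_all_centers cv_within_centers_median
#> 1              te_ms          0.174                    0.115
#> 2   pixel_spacing_mm          0.328                    0.221
#> 3 slice_thickness_mm          0.229                    0.124
#> 4          n_bvalues          0.551                    0.346
#> 5     highest_bvalue          0.092                    0.074
```

The b-value sensitivity analysis over the 45 scans with ≥ 6 b-values gives a
mean ADC decrease of 2.5% per 100 s/mm² of highest b-value at the default
noise level (2.8% in the noise-free calibration), and the longitudinal
four-combination analysis shows how switching between the highest and
second-highest b-value between timepoints shifts each patient's measured
ADC change.

The whole pipeline, including all output tables, runs as

```r
runPipeline(defaultCohortConfig(), "results/run1", seed = 42)
```

or from a shell via `Rscript inst/scripts/adcvar.R run-all --seed 42 --out results/run1`.

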