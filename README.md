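# adctrack

Weekly tumor response assessment from diffusion-weighted MRI (DW-MRI).

## The problem

Grossly involved lymph nodes in head-and-neck cancer often become cystic
under chemoradiotherapy instead of shrinking, so morphological (volume)
imaging alone is a poor guide for mid-course adaptive replanning. The
apparent diffusion coefficient (ADC) — the voxel-wise rate constant of
diffusion-driven signal decay, in mm²/s — rises early in responding tumors
as cells die and extracellular water increases, and typically changes weeks
before the volume does. `adctrack` implements the quantitative pipeline for
tracking that functional response weekly:

1. **ADC mapping.** From signal volumes `S(b)` at two or more diffusion
   weightings `b` (s/mm²), fit the monoexponential model per voxel:

   `S(b) = S(0) · exp(−b · ADC)`

   Two-point acquisitions (b = 0 and a high b, e.g. 800 s/mm²) use the
   closed form `ADC = ln(S(0)/S(b)) / b`; more b-values use ordinary least
   squares on `ln S(b)` vs `b`.

2. **Viable-tumor isolation.** Cystic/necrotic subregions have high ADC and
   make the whole-GTV (gross tumor volume) histogram bimodal, corrupting
   trend analysis. The viable compartment is isolated by Boolean
   subtraction: `viable = GTV AND NOT cystic`. A seeded Gaussian-mixture
   helper (`split_components`) flags bimodal histograms as a decision aid.

3. **First-order histogram statistics** of viable-tumor ADC: mean, median,
   SD, 10/25/75/90th percentiles, skewness (Fisher–Pearson g1) and excess
   kurtosis (normal → 0), plus ROI volume in cm³.

4. **Longitudinal response.** Absolute and percent change of any metric
   versus the pretreatment (week 0) baseline; week-over-week trend labels
   (increase / plateau / decrease); an early-change response rule (default:
   flag when median-ADC change at week 3 is strictly below +25%); and
   cohort-level Tukey box-plot summaries.

5. **Agreement statistics.** Interobserver agreement as the two-way
   random-effects, absolute-agreement, single-rater ICC(2,1) with an
   F-method 95% CI, and Pearson correlation (t-transform p-value) between
   functional (ADC) and morphological (volume) change.

6. **Digital phantom.** A seeded synthetic-cohort generator (`phantom_spec`
   / `generate_phantom`) emulating the assumed data structure: ellipsoidal
   viable (log-normal ADC, median 1.19 × 10⁻³ mm²/s pretreatment) and
   cystic (truncated-normal, 2.4 × 10⁻³ mm²/s) compartments, weekly
   median-ADC and volume multiplier schedules, and Rician magnitude noise —
   so the full pipeline is testable without patient data. Minimal NIfTI-1
   I/O is built in.

## Worked example

```r
library(adctrack)

spec <- phantom_spec(seed = 20)          # default 64x64x28 weekly phantom
ph   <- generate_phantom(spec)
s    <- phantom_to_series(ph, "node_1")  # ADC fit + viable isolation per week

percent_change(s, "median_adc")[, c("week", "value", "percent_change")]
#>   week    value percent_change
#> 1    0 0.001187            0.0
#> 2    1 0.001354           14.1
#> 3    2 0.001484           25.0
#> 4    3 0.001664           40.2
#> 5    4 0.001690           42.4
#> 6    5 0.001723           45.1
#> 7    6 0.001880           58.3

classify_response(s)   # default rule: < 25% at week 3 flags poor response
#> <response_call> node_1: not_flagged (40.2% at week 3; rule: < 25% at week 3)

classify_trend(s)$label
#> "increase" "increase" "increase" "plateau" "plateau" "increase"
```

The week-3 change of +40.2% clears the 25% threshold, so this node is not
flagged; the trend shows the typical early rise then plateau. The whole-GTV
histogram, by contrast, is bimodal until the cystic component is removed:

```r
w0  <- ph$weeks[[1]]
adc <- fit_adc_pair(w0$series)
split_components(extract_values(adc, w0$masks$gtv), seed = 1)
#> <component_split> verdict: BIMODAL
#>   means 0.001193 / 0.002265  sds 0.000176 / 0.000444  weights 0.89 / 0.11
summarize_histogram(extract_values(adc, w0$masks$viable))
#> <histogram_summary> n=3360  mean=0.001203  median=0.001187  sd=0.000189
#>   p10/p25/p75/p90 = 0.0009717/0.00107/0.001322/0.001447  skew=0.479  exkurt=0.444
```

The recovered mixture means sit at the two compartments' ADC levels, and
the viable-only histogram is unimodal and positively skewed, as expected
pretreatment.

## Command line

An Rscript front-end is installed at `inst/cli/adctrack` (the exported
`run_cli()` takes the same arguments in-process):

```sh
adctrack simulate  --config phantom.yaml --out sim/ --seed 7
adctrack adc-map   --b0 sim/week0_b0.nii.gz --bhigh sim/week0_b800.nii.gz \
                   --bvalue 800 --out adc.nii.gz
adctrack analyze   --adc adc.nii.gz --gtv sim/week0_mask_gtv.nii.gz \
                   --cystic sim/week0_mask_cystic.nii.gz --week 0 --out w0.csv
adctrack cohort    --manifest manifest.csv --metric median_adc \
                   --decision-week 3 --threshold 25 --out reports/
adctrack agree     --ratings ratings.csv --out icc.json
adctrack correlate --pairs pairs.csv --out cor.json
```

All commands are byte-deterministic given the same seed and inputs.

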