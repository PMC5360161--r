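---
title: "Weekly ADC-based response assessment: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weekly ADC-based response assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adctrack)
```

## Scope and model

`adctrack` quantifies the weekly functional response of tumors — in the
motivating application, grossly involved neck lymph nodes under concurrent
chemoradiotherapy — from diffusion-weighted MRI. The physical model is the
monoexponential decay of the diffusion signal with b-value,

$$S(b) = S(0)\,e^{-b\,\mathrm{ADC}},$$

where $b$ (s/mm²) is the diffusion weighting and ADC (mm²/s) the apparent
diffusion coefficient. For a two-point acquisition with $b \in \{0, b_h\}$
the fit is the closed form $\mathrm{ADC} = \ln(S(0)/S(b_h))/b_h$; for more
b-values, `fit_adc_multib()` takes the negative OLS slope of $\ln S(b)$ on
$b$. The two agree exactly (to floating tolerance) in the two-point case.
All stored ADC values are plain mm²/s; the conventional display scale
×10⁻³ mm²/s is a presentation choice left to the caller.

Assumptions worth stating: a single diffusion compartment per voxel
(no intravoxel incoherent motion / perfusion term, no kurtosis term), raw
magnitude signals (no Rician-bias or noise-floor correction), and
co-registered inputs. Masks must already live on the ADC grid — the package
refuses to resample rather than hide a registration error.

### Handling of non-physical voxels

The logarithm is undefined where either signal is ≤ 0, so such voxels are
marked invalid and excluded from every downstream statistic. Noise can also
produce $S(b_h) > S(0)$ and hence a negative ADC. The policy is
configurable (`retain` / `clip` / `invalidate`) and defaults to **retain**:
the source analyses fitted raw signals without mention of censoring, and
dropping or clipping the negative tail would bias the low end of the
histogram; the count of negative-ADC voxels is reported so the user can
judge the noise regime.

## Viable-tumor isolation and histogram statistics

Cystic/necrotic subregions carry high ADC (lost membrane integrity, long
diffusion paths) and, when prominent, make the whole-GTV ADC histogram
bimodal; trend analysis on the mixed histogram is unreliable. The pipeline
therefore analyzes ADC on the **viable** compartment, constructed by
Boolean subtraction `viable = GTV AND NOT cystic` (`subtract_rois()`).
Volume statistics, by contrast, always use the **entire** GTV including
cystic parts, matching clinical volumetric practice. Volumes are voxel
count × voxel volume, reported in cm³.

`summarize_histogram()` computes first-order descriptors with pinned
conventions, since the upstream literature leaves them unstated:

* percentiles: linear interpolation between order statistics
  (`quantile` type 7) — the most common convention, frozen so the test
  oracles are well-defined;
* SD with the $n-1$ denominator;
* skewness: Fisher–Pearson $g_1 = m_3 / m_2^{3/2}$ (population moments,
  not bias-corrected);
* kurtosis: **excess** kurtosis $m_4/m_2^2 - 3$, so a Gaussian histogram
  reads 0 — this is the convention that makes "initially Gaussian,
  kurtosis ≈ 0" statements meaningful.

Degenerate inputs (constant lists, $n < 3$) flag skewness/kurtosis as
undefined rather than emitting a number.

`split_components()` fits a two-component Gaussian mixture to an ROI's ADC
values (seeded EM, k-means initialisation) and calls the histogram bimodal
only when BIC prefers two components **and** the component means are more
than one pooled within-component SD apart. The second condition matters: on
skewed-but-unimodal data BIC alone happily prefers two overlapping
Gaussians. The verdict is advisory — no threshold-based segmentation of
clinical utility was found in this setting, so the pipeline never
auto-subtracts a fitted component; isolation always comes from an explicit
cystic mask.

## Longitudinal response

Weeks are aligned by index (0 = pretreatment); scan-day metadata is carried
but never used for alignment, and missing weeks are excluded, not
interpolated. For a metric $v$ (median ADC by default),

$$\%\Delta_w = 100\,(v_w - v_0)/v_0 ,$$

so a week-6 value of 1.58× baseline reads as +58%.

* `classify_trend()` labels each week-over-week interval increase /
  plateau / decrease; *plateau* means the step is within ±5% of the
  baseline value. The 5% default is this package's convention (documented
  as such, configurable), chosen to be comfortably above the ~0.3%
  sampling noise of a median over thousands of voxels yet below the
  10–16 percentage-point weekly steps seen during active response.
* `classify_response()` implements the early-change rule: flag as
  suspected poor responder when $\%\Delta$ at the decision week is
  **strictly below** the threshold. Defaults: threshold 25%, decision
  week 3 — the threshold follows the published early-ADC-change criterion
  and week 3 the observation that functional change saturates around then,
  making weeks 3–4 the natural replanning window. Both are parameters. The
  strict inequality is a deliberate reading: a node sitting exactly at
  +25.0% is *not* flagged. (The motivating slow-responder case is printed
  in the source material as 25% at week 3 yet described as "less than
  25%"; the strict rule is adopted and the ambiguity documented rather
  than resolved.)
* `cohort_summary()` aggregates many series into per-week Tukey box
  statistics (type-7 quartiles, whiskers at the most extreme observation
  within 1.5 × IQR, outliers beyond). A cohort's population percent change
  can be read either as the median of per-GTV percent changes (what
  `value = "percent_change"` computes) or as the percent change of per-week
  cohort medians; the two differ in general, and the package computes the
  former while leaving the latter one `percent_change()` call away.

## Agreement statistics

Interobserver agreement uses ICC(2,1): two-way random effects, absolute
agreement, single rater. This form treats the radiologists as
interchangeable random raters and charges systematic offsets against
agreement — the right choice when the question is whether two readers'
median-ADC series can be used interchangeably. It is computed from the
two-way ANOVA mean squares with the F-method 95% CI (Satterthwaite degrees
of freedom). The implementation was cross-validated against an independent
reference implementation during development; the shipped tests verify it
against a hand-computed mean-squares oracle. Note the F-based interval is
approximate: in simulations its coverage is near-nominal (~95%) when rater
variance is small relative to target variance (the regime of interest
here), but can dip toward ~89% when rater offsets rival the error variance.

Pearson correlation between functional and morphological change uses the
sample $r$ with the two-sided p-value from $t = r\sqrt{(n-2)/(1-r^2)}$ on
$n-2$ df. Incomplete rating rows and incomplete pairs are dropped with a
warning, never imputed.

## The digital phantom: what it emulates, and what it does not

No imaging data are deposited with the source study, so the package ships a
seeded phantom generator whose defaults *are* the stated world the
analysis assumes:

| parameter | default | rationale |
|---|---|---|
| grid / voxel | 64×64×28 at 1.7×1.7×5 mm | 5 mm slices, 28 slices as acquired; 1.7 mm ≈ 220 mm FOV / 128 (in-plane resolution is not printed; tests that need the full 128×128 matrix build it explicitly) |
| b-values | {0, 800} s/mm² | the acquisition protocol |
| viable ADC | log-normal, median 1.19 × 10⁻³ mm²/s, σ_log = 0.15 | printed pretreatment median; log-normal guarantees positivity and reproduces the positive skew/kurtosis of pretreatment histograms (σ_log = 0.15 gives g₁ ≈ 0.46, matching "mildly skewed, near-Gaussian") |
| cystic ADC | normal truncated at 0, mean 2.4 × 10⁻³ mm²/s, sd 0.3 × 10⁻³ | only "high ADC" is reported; 2.4 × 10⁻³ is a placeholder above the viable range, not a literature value |
| ADC schedule | ×{1, 1.14, 1.25, 1.41, 1.42, 1.45, 1.58} | the printed weekly percent increases 14…58% |
| volume schedule | ×{1, 0.92, 0.90, 0.84, 0.78, 0.60, 0.58} | the printed weekly volume decreases 8…42% |
| cystic geometry | ellipsoid, ~9% of GTV volume by default | unreported; a persistent necrotic node can reach ~30% (a 5 cm³ necrotic volume in a 16.5 cm³ node), which the tests construct explicitly |
| S(0) levels | tissue 1000, background 60 (a.u.) | arbitrary-unit MR magnitudes |
| noise | Rician, σ = 15 | magnitude-MR noise model `sqrt((S+g₁σ)² + (g₂σ)²)`; σ = 15 gives SNR ≈ 67 at b=0 and ≈ 26 at b=800 in tumor, a realistic clinical EPI regime |
| background ADC | 0.8 × 10⁻³ mm²/s | gives the noiseless round-trip invariant meaning outside the tumor too |

Weekly volumes scale the ellipsoid semi-axes by the cube root of the volume
multiplier; the viable ADC distribution is scaled multiplicatively, so the
true (distributional) median reproduces the schedule exactly before noise.
Where viable and cystic geometry overlap, cystic wins — mirroring the
subtraction construction. A single integer seed drives all draws; identical
seeds give bit-identical output, and masks/ground truth are independent of
the seed.

**What the phantom does not emulate** (hence what a green test does not
establish): anatomically realistic geometry, susceptibility/EPI distortion,
coil-sensitivity inhomogeneity, partial-volume voxels, registration error,
or interobserver contouring variability. Recovery of the ADC schedule on
the phantom validates the *estimator chain*, not the clinical claims.

## Numerical choices and degenerate inputs

* NIfTI-1 I/O is implemented minimally in-package (no NIfTI reader exists
  in the target R stack): single-file `.nii`/`.nii.gz`, uint8/int16/int32/
  float32/float64, slope/intercept scaling honored on read, axis-aligned
  RAS sform from the voxel spacing on write, both byte orders read,
  little-endian written. Quaternion qforms, extensions, and 4-D series are
  out of scope and rejected loudly.
* The EM mixture floors component SDs at 10⁻⁶ of the sample SD to avoid
  variance collapse, converges on relative log-likelihood below 10⁻¹⁰, and
  derives its BIC penalty from 2 vs 5 free parameters.
* Empty ROIs, empty viable masks after subtraction, zero baselines,
  constant correlation inputs, and zero between-target variance in the ICC
  all raise informative errors (or warnings with defined fallbacks, where
  the spec of the operation says so) rather than NaNs.
* `compute_volume()` multiplies the voxel count by the pre-divided voxel
  volume so that generator ground truth and pipeline volumes agree to the
  last bit, keeping the volume-additivity invariant exact.

## Known limitations

* The monoexponential model overestimates ADC when perfusion is present
  (no IVIM term); this is inherent to two-b-value acquisitions.
* `split_components()` assumes at most two components and Gaussian shape;
  heavily skewed single-compartment data with separation just above one
  pooled SD can be called bimodal.
* The ICC confidence interval is an F-approximation (see above).
* The CLI covers the analysis path end to end but performs no DICOM
  conversion or registration; inputs must be co-registered NIfTI.
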