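# ivimpref

Voxel-wise IVIM/ADC model fitting and model-preference analysis for
diffusion-weighted MRI, with the repeatability and longitudinal statistics
needed to validate the resulting biomarkers. The package is aimed at
quantitative-imaging researchers who want a tested, reproducible
implementation of the full chain — signal models, segmented fitting, AICc
model comparison, ROI biomarkers, test-retest and treatment-response
statistics — exercised end-to-end on synthetic digital phantoms with known
ground truth.

## The models and statistics at its core

Diffusion-weighted MRI signal at weighting *b* (s/mm²) is described either
by the mono-exponential apparent-diffusion-coefficient model,
S(b) = S₀·exp(−b·ADC), or by the bi-exponential intra-voxel incoherent
motion (IVIM) model,

    S(b) = S₀ [ f·exp(−b·D*) + (1 − f)·exp(−b·D) ],

which separates slow tissue diffusion (D) from fast capillary
pseudo-diffusion (D*), with f the perfusion signal fraction. Diffusivities
are in µm²/ms throughout.

Per voxel, the package fits

* **ADC_b0** — mono-exponential over all b-values (perfusion-sensitive);
* **ADC_b150** — mono-exponential over b ≥ 150 s/mm² (perfusion-suppressed);
* **IVIM** — segmented: log-linear high-b fit for D, f from the intercept,
  then 1-D bounded least squares for D* with S₀ pinned to the measured b=0
  signal, swept over cut-offs {100, 150, 300} s/mm² and scored by residual
  sum of squares.

The two models are compared voxel-wise with the corrected Akaike
information criterion, AICc = n·ln(SSR/n) + 2k + 2k(k+1)/(n−k−1); the
lower-AICc model is "preferred". From the preference map come

* **p_IVIM** — the fraction of valid ROI voxels in which IVIM is preferred,
  a biomarker of how much of a region carries a measurable perfusion
  component;
* **δADC** — the ROI median of voxel-wise ADC_b0 − ADC_b150, quantifying
  the perfusion-dependent bias incurred by including b = 0 in ADC fits.

ROI biomarkers feed three statistics: the within-subject coefficient of
variation (wCV, test-retest repeatability), one-way repeated-measures
ANOVA with Bonferroni-corrected post-hoc paired contrasts (longitudinal
change), and the repeated-measures correlation (within-subject association,
e.g. δADC vs f).

## Worked example

```r
library(ivimpref)

spec <- phantom_spec("two_region", snr_b0 = 100, noise_model = "gaussian",
                     seed = 1, dim = c(16, 16, 2))
ph   <- generate_phantom(spec)          # perfused tissue | fluid phantom
maps <- fit_dwi_volume(ph$dwi)          # voxel-wise ADC + IVIM + AICc
pref <- build_preference_map(maps)

print(maps)
#> IVIM/ADC map set 16 x 16 x 2: 512 valid, 0 excluded, 109 f-clamped
#> IVIM preferred in 258 voxels, ADC in 254

p_ivim(pref, ph$mask, 1)   # perfused tissue (true f = 0.19)
#> [1] 1
p_ivim(pref, ph$mask, 2)   # fluid (true f = 0)
#> [1] 0.0078125

summarize_roi(maps, ph$mask, 1)[, c("median_D", "median_f",
                                    "median_delta_adc", "p_ivim")]
#>   median_D median_f median_delta_adc p_ivim
#>      1.312   0.1864           0.3017      1
```

The tissue region (true D = 1.3 µm²/ms, f = 0.19) is recovered with a
median D of 1.31 and median f of 0.186; every tissue voxel prefers the
bi-exponential model while essentially no fluid voxel does, and the
perfusion bias δADC ≈ 0.30 µm²/ms shows how far a b=0-anchored ADC
overshoots the perfusion-suppressed one in this well-perfused class.

A thin command-line wrapper over the same pipeline functions is installed
at `inst/cli/ivimprefmap.R`
(`simulate | fit | summarize | stats`, see `--help`).

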