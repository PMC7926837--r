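# lutracer

Voxel-based dosimetry and lesion kinetics for ^177^Lu radioligand
therapy (RLT) of metastatic prostate cancer.

Post-therapy quantitative SPECT/CT delivers activity-concentration maps
(Bq/mL) at a few time points per therapy cycle. `lutracer` turns those
maps into absorbed doses and response summaries:

* **Kinetics** — region/voxel time–activity curves; mono-exponential
  fits $A(t) = A_0 e^{-\lambda_{\rm eff} t}$ with
  $T_{1/2,\rm eff} = \ln 2 / \lambda_{\rm eff}$; time-integrated
  activity by piecewise-exponential integration, a global fit
  ($\tilde A = A_0/\lambda_{\rm eff}$), or the single-scan estimator
  $\tilde A = A(T)\, 2T/\ln 2$. Extrapolated clearance is clamped at
  the ^177^Lu physical decay constant.
* **Dosimetry** — voxel dose by local energy deposition
  ($D = \tilde A \cdot 3600 \cdot \Delta_{np} / 10^{-3}$ Gy per Bq·h/mL,
  appropriate because the ^177^Lu electron range is below the 1.95 mm
  voxel scale) or by voxel S-value kernel convolution; MIRD-style organ
  self-dose; Gy/GBq normalisation; partial-volume compensation
  $D = \bar D_{\rm VOI} \times V_{\rm VOI} / V_{\rm CT}$ for small
  structures.
* **Quantification** — SUV maps, SUVmax with an adaptive 40%-isocontour
  VOI, metabolic tumor volume (SUV > 3.5, connected components).
* **Response** — PSA / SUVmax / tumor-burden percent changes classified
  under EORTC, PERCIST 1.0 and a PCWG-style PSA threshold.
* **Tracking** — per-lesion multi-cycle trajectories with explicit N/A
  semantics, group mean doses, fold changes and washout-slope
  comparisons, exercised on a bundled transcription of a published
  four-cycle six-lesion clinical case series.
* **Phantoms** — digital multi-time-point phantoms with analytic ground
  truth (ellipsoids, mono-exponential kinetics, Gaussian PSF,
  multiplicative noise, fully seeded) so the whole chain is testable
  without scanner data.

## Worked example

A 10 mm lesion with a 25 h effective half-life, imaged at 4/24/48 h
through a 10 mm PSF — the partial-volume regime:

```r
library(lutracer)

sp <- phantom_spec(
  regions = list(region_spec("lesion", "lesion",
                             center_mm = c(62.4, 62.4, 62.4),
                             radii_mm = 5, A0_Bq_per_ml = 5e4,
                             lambda_per_h = log(2) / 25)),
  psf_fwhm_mm = 10, seed = 1)
ph <- build_phantom(sp, time_points_h = c(4, 24, 48))

fit <- fit_monoexp(extract_tac(ph, ph$masks$lesion, statistic = "mean"))
fit
#> mono-exponential fit, region 'lesion' (3 samples)
#>   A0        = 9383.76 Bq/mL
#>   lambda_eff= 0.0277259 1/h
#>   T1/2_eff  = 25 h
#>   R^2 (log) = 1.0000
```

The half-life is recovered exactly (spatial blur commutes with the
temporal decay), but the fitted `A0` is 9384 Bq/mL against a true
50000 Bq/mL — the partial-volume loss. Doses show the same bias and its
compensation:

```r
tia  <- tia_map_voxelwise(ph, scheme = "monoexp_global")
dose <- dose_local_deposition(tia)

sig <- 10 / 2.3548                      # PSF sigma in mm
cx  <- (seq_len(64) - 0.5) * 1.95 - 62.4
voi <- region_mask(outer(outer(cx^2, cx^2, `+`), cx^2, `+`)
                     <= (5 + 3.5 * sig)^2,
                   "lesion_voi", "lesion", 1.95,
                   ct_volume_ml = ph$masks$lesion$ct_volume_ml)
organ_dose_report(tia, list(voi), injected_activity_MBq = 7395,
                  dose_map = dose)
#>       region mean_dose_Gy corrected_dose_Gy dose_Gy_per_GBq voi_volume_ml
#> 1 lesion_voi  0.001950118         0.1537807      0.02079523      32.74409
ph$truth$mean_dose_Gy
#> [1] 0.1538387
```

The volume-ratio compensation recovers the ground-truth mean dose to
0.04%, while the raw mean over the tight CT mask is low by two orders
of magnitude here (most of the signal of a 10 mm sphere is smeared
outside it by a 10 mm PSF).

Response metrics and the bundled case series:

```r
percent_change(154.2, 24.6)                      # PSA after cycle 1
#> [1] 84.04669
classify_psa_response(percent_change(154.2, 24.6))$category
#> [1] "PR"
classify_suv_response(80.7, "PERCIST")
#> [1] "PR"
group_mean_dose(case_lesion_records(), "bone", 1,
                case_mean_injected_GBq())        # mean skeletal dose, Gy
#> [1] 38.33075
```

An end-to-end run (`run_pipeline()`, or the `inst/cli/lutracer.R`
wrapper with `run` / `simulate` / `dose` / `quantify` / `respond` /
`track` subcommands) writes CSV tables plus a JSON manifest recording
the seed and configuration hash; identical configurations produce
byte-identical outputs.

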