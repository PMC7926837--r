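---
title: "Voxel-based dosimetry and lesion kinetics for Lu-177 radioligand therapy"
author: "lutracer authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based dosimetry and lesion kinetics for Lu-177 radioligand therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lutracer)
```

## The problem

Radioligand therapy (RLT) of metastatic castration-resistant prostate
cancer with ^177^Lu-labelled PSMA inhibitors deposits most of its energy
through short-range beta and conversion electrons. The absorbed dose a
lesion or organ receives is therefore driven by how much activity it
accumulates and how long the activity resides there. Post-therapy
quantitative SPECT/CT at a few time points (typically 4, 24 and 48 h
after injection) is the practical way to measure both, and `lutracer`
implements the full chain from those activity maps to per-lesion,
per-cycle dose and response summaries:

1. **Phantom simulation** — multi-time-point activity maps with known
   kinetics, point-spread blurring and noise, so every downstream stage
   can be validated against analytic ground truth.
2. **Kinetics** — region and voxel time–activity curves (TACs),
   mono-exponential fits, time-integrated activity (TIA).
3. **Dosimetry** — voxel absorbed dose by local energy deposition or
   dose-kernel convolution, organ-level (MIRD-style) self-dose,
   partial-volume compensation, Gy/GBq normalisation.
4. **Quantification** — SUV maps, SUVmax with an adaptive isocontour
   VOI, metabolic tumor volume (MTV).
5. **Response** — PSA and SUV/MTV percent changes with EORTC, PERCIST
   and PSA-threshold classification.
6. **Tracking** — per-lesion multi-cycle trajectories and cross-cycle
   summaries, exercised on a bundled transcription of a published
   four-cycle, six-lesion clinical case series.

## Models and assumptions

### Mono-exponential washout

A region's concentration is modelled as $A(t) = A_0 e^{-\lambda_{\rm
eff} t}$ with $\lambda_{\rm eff} = \lambda_{\rm phys} + \lambda_{\rm
biol}$. With only two or three samples per curve — the reality of
post-therapy imaging — a straight-line least-squares fit of
$\ln A$ against $t$ is the only model the data support; it is exact for
two samples, and `fit_monoexp()` reports $A_0$, $\lambda_{\rm eff}$,
$T_{1/2,\rm eff} = \ln 2/\lambda_{\rm eff}$ and the log-scale $R^2$.
A perfectly flat curve is flagged degenerate ($\lambda_{\rm eff}=0$,
infinite half-life) rather than silently integrated.

### Time-integrated activity

`time_integrated_activity()` offers three schemes:

* **piecewise_exp** (default in the pipeline): linear rise from zero to
  the first sample, exact exponential interpolation between samples, and
  a mono-exponential tail using the last segment's decay constant. No
  data exist before the first scan, so the rise shape is an assumption;
  the linear rise is the conservative standard choice and a `plateau`
  (instantaneous-uptake) alternative is available. With samples at
  4/24/48 h the linear rise replaces about 5.8% of the closed-form
  $A_0/\lambda$ area on an exactly mono-exponential curve — users
  comparing schemes should expect that difference; it is the uptake
  assumption, not an integration error (the scheme agrees with a
  0.01 h quadrature of its own interpolant to better than 0.1%).
* **monoexp_global**: $A_0/\lambda$ from a single fit over all samples.
* **single_time_point**: from one sample $(T, A)$,
  $\tilde A = A \cdot 2T/\ln 2$ — the simplified one-scan protocol. It
  is exact when $T$ equals the effective half-life, which is why a
  single scan around day 4 works well for ^177^Lu compounds whose
  lesion half-lives approach 100 h; for the short lesion half-lives in
  the bundled case (20–30 h) a 96 h scan would overestimate the TIA,
  so the scheme choice is recorded in every report.

Biological clearance can only accelerate physical decay, so every
extrapolated decay constant (tail or global) is clamped from below at
$\lambda_{\rm phys}$ (`clamp_to_physical = TRUE`); with the clamp off, a
non-positive constant is an error because the integral diverges. An
exact-zero final sample truncates the integral at that time (the lesion
is gone).

### Absorbed dose

The mean non-penetrating energy of ^177^Lu (beta plus conversion/Auger
electrons) is 147.9 keV per decay by default, configurable in
`lu177_constants()` together with the 6.647 d physical half-life.
Tissue density is fixed at 1 g/mL; a CT density map is out of scope and
bone-density refinement is a documented limitation.

Because the electron range is below the 1.95 mm voxel scale, **local
energy deposition** is the default engine:
$D = \tilde A \cdot 3600 \cdot \Delta_{np} / (10^{-3}\,{\rm kg/mL})$ Gy
per voxel, independent of voxel size. The **kernel engine** convolves
per-voxel decays with an odd-sized voxel S-value table; a delta kernel
reproduces local deposition exactly (to machine precision), and any
kernel normalised to $\Delta_{np}$ conserves total energy. Per-voxel
TIA (`tia_map_voxelwise()`) matches the "voxel-based" method; the
per-region mode (`tia_map_regional()`) fits the region-mean TAC once
and is the fast path for uniform-kinetics scenarios.

### Partial-volume compensation

Structures small relative to the scanner PSF lose apparent dose by
spill-out. The compensation implemented in `eq1_pve_correct()` rescales
the mean dose over a measurement VOI large enough to contain the
smeared signal by the ratio of VOI volume to the anatomical (CT) volume
of the structure:

$$D = \bar D_{\rm VOI} \times \frac{V_{\rm VOI}}{V_{\rm CT}}.$$

This is exact up to the fraction of smeared signal escaping the VOI,
because blurring conserves total activity. Two quantitative points the
phantom study makes precise:

* The mean over the *true* mask of a blurred uniform sphere of radius
  $R$ recovers only $1 - 1.1968\,\sigma/R + O((\sigma/R)^3)$ of the
  true value ($\sigma = {\rm fwhm}/2.3548$; derived from the sphere's
  autocorrelation against the Gaussian kernel). At a diameter of
  5 fwhm that is still a 20% deficit; the raw mean reaches 95% only
  for diameters around 24 fwhm. "Large organs need no correction" is
  therefore a statement about organs *much* larger than the PSF — the
  acceptance study uses a 100 mm organ against a 4 mm PSF (measured
  recovery 96%).
* On a digital phantom the anatomy is inherently voxelised: a 6 mm
  sphere on a 1.95 mm grid occupies 8 voxel centres (0.059 mL) versus
  0.113 mL analytically. The faithful emulation of "volume measured on
  CT" is the mask volume, which is what `build_phantom()` attaches to
  each mask; the analytic ellipsoid volume is kept in the ground truth
  so that voxelisation error remains visible.

In the per-region report (`organ_dose_report()`) the compensation is
applied only when the CT volume is known and below a threshold
(default 25 mL — small organs and lesions), mirroring clinical practice
where large-organ VOIs match the anatomy.

### SUV, MTV and response

SUV uses body-weight normalisation,
${\rm SUV} = C[{\rm kBq/mL}]/(A_{\rm inj}[{\rm MBq}]/W[{\rm kg}])$;
patient weight is mandatory (the pipeline aborts the SUV stage without
it). `suvmax_in_voi()` grows the measurement VOI adaptively as the
connected component, at or above 40% of SUVmax, containing the maximum
voxel. `mtv()` uses a strict `>` at the threshold (default SUV 3.5) and
26-connectivity, both configurable; ties at the threshold are excluded
because the behaviour of clinical tools there is unspecified, and the
strict rule is the reproducible choice. Physiological uptake (kidneys,
bladder, gut) is removed via user-supplied exclusion masks.

Response classification: EORTC (PR at a decrease > 25%, PD at an
increase > 25% or a new lesion), PERCIST 1.0 (≥ 30% both ways), PSA by
the PCWG-style 50% threshold (configurable — the bundled case labels an
84% drop a partial response without stating its threshold). Both SUV
criteria are applied to SUVmax rather than SULpeak: quantitative SPECT
provides no lean-body-mass SUL, and the case series recorded SUVmax;
this is a deliberate, documented deviation from strict PERCIST.

## What the phantom emulates — and what it does not

`build_phantom()` produces ellipsoidal regions with voxel-centre
membership (the simplest reproducible voxelisation), instantaneous
uptake, mono-exponential washout, Gaussian PSF blur (physics first) and
then multiplicative Gaussian noise (measurement second), all
deterministic given the seed. Defaults mirror the modelled acquisition:
64³ grid, 1.95 mm voxels, scans at 4/24/48 h. The scanner PSF is never
published for this system, so the 10 mm fwhm default is a realistic
post-reconstruction value chosen once for the test conditions; noise
defaults to off so that deterministic examples stay exact, and the 5%
multiplicative fraction used in the noisy studies is a typical
quantitative-SPECT repeatability figure.

The phantom does **not** simulate projection/reconstruction (collimator
response, scatter, attenuation), registration error between time
points, heterogeneous intra-lesion kinetics, or background uptake from
adjacent organs unless an explicit background region is added. Passing
phantom tests therefore demonstrates correctness of the *analysis
chain*, not robustness to every error source of real serial SPECT —
registration error in particular is declared out of scope (masks must
share the exact grid; the package never resamples).

## Numerical choices

* Gaussian taps are discrete-normalised to unit sum, so blurring
  conserves total activity exactly for in-grid support; convolution is
  separable shift-and-add.
* Kernel convolution supports zero padding (default) and periodic
  padding (infinite-medium equilibrium checks).
* Per-voxel fits are evaluated in closed form, vectorised; voxels with
  any non-positive sample get TIA 0 (they carry no integrable signal).
* Connected components use breadth-first flood fill with 26- or
  6-connectivity; the test suite cross-checks against an independent
  graph-library oracle.
* Problem sizes in the routine test run are kept small (16³–32³ grids);
  the acceptance study runs the full 64³ clinical matrix, 50 noisy
  phantom replicates for the compensation study and 100 for kinetics
  recovery — sizes chosen so the whole study completes in well under a
  minute on one core while keeping Monte-Carlo fractions stable at the
  percent level.

## The bundled case series

`inst/extdata/case_*.csv` transcribe, exactly as printed, the lesion
dose (Gy/GBq), lesion volume/SUVmax and organ dose tables of a
published single-patient four-cycle ^177^Lu-PSMA I&T case, together
with its PSA and tumor-burden series. Per-cycle administered activities
were not published — only the 7395 MBq mean — so Gy conversions use the
mean (`case_mean_injected_GBq()`) and reports record that. Statuses
distinguish `resolved` (the local node disappeared after two cycles;
its SUVmax entries end there) from `not_measurable` (bone lesions below
SPECT detectability in late cycles while their volumes, outlined on CT,
persist). One transcription quirk is preserved deliberately: the dose
table still carries automated VOI read-outs for the resolved node at
cycles 3–4, while its SUV table entries are N/A; the record contract
therefore constrains SUVmax, not dose, in resolved cycles. Sparse
4 h/48 h entries for the para-aortic node in late cycles are likewise
reproduced as printed.

## Known limitations

* Uniform unit density; no photon cross-dose between organs, no
  bone-marrow dosimetry, no Monte-Carlo transport.
* Mono-exponential kinetics only — no bi-exponential or compartmental
  models, no uptake-phase data before the first scan.
* No DICOM ingestion and no image registration; inputs are NIfTI
  volumes on a common grid.
* Response classification operates on the numbers it is given;
  SULpeak-based strict PERCIST is not implemented.
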