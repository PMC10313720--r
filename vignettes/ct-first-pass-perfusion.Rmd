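---
title: "Two-scan CT perfusion: models, synthetic cohort, and timing optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-scan CT perfusion: models, synthetic cohort, and timing optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctperf)
```

## The problem

Dynamic contrast-enhanced CT perfusion quantifies tissue blood flow (BF, in
ml/100 ml/min) from the evolution of attenuation after an iodine bolus, and
is a candidate imaging biomarker for pancreatic adenocarcinoma, where
carcinoma perfuses markedly below healthy parenchyma. Its clinical weakness
is dose: a full dynamic acquisition covers the bolus passage with dozens of
volume scans. First-pass analysis (FPA) replaces the series with **two**
scans, cutting dose by roughly the ratio of acquisition counts, provided the
two scans are timed correctly relative to the bolus. This package implements
both estimator families, a prospective timing rule for the second scan, and a
synthetic dynamic-CT cohort with known ground truth on which all of it is
validated.

## Models

**Maximum slope model (MSM).** Under the indicator-dilution assumption that
no contrast has yet left the tissue compartment, the tissue time-attenuation
curve (TAC) satisfies

$$\mathrm{BF} = 6000\,\frac{\max_t\, d\mathrm{TAC}/dt}{\mathrm{AIF}_{max}\cdot\rho_t},$$

with the arterial input function (AIF) measured in the abdominal aorta,
$\rho_t$ the tissue density (default 1 g/ml, giving per-volume flow) and 6000
the single units factor (`HU_FLOW_SCALE`) converting (HU/s)/HU into
ml/100 ml/min. `msm_map()` estimates the peak upslope per voxel as the
maximum over sliding windows of the least-squares slope of HU versus time.

**First-pass analysis (FPA).** Integrating the same assumption between two
scan times $t_1$ (the bolus-tracking trigger, AIF just above 120 HU absolute)
and $t_2$ gives, per voxel,

$$P_{FPA} = 6000\, \frac{\Delta HU}{\int_{t_1}^{t_2} \mathrm{AIF}_{enh}(t)\,dt},$$

where $\Delta HU$ is the voxel's enhancement change between the scans and the
denominator integrates the AIF enhancement above baseline (trapezoid on the
frame grid). Tissue enhancement proxies contrast concentration and per-voxel
volume normalization replaces compartment mass — the standard concretization
of the first-pass mass-balance argument for CT. Writing the compartment
average $P_{avg} = 6000\,\Delta HU_{avg}/\int \mathrm{AIF}_{enh}$ and
redistributing voxelwise as $P_{FPA} = P_{avg}\,\Delta HU / \Delta HU_{avg}$
is algebraically the same map; `fpa_map()` computes both and asserts the
conservation law (compartment mean of the raw map equals $P_{avg}$ to
floating precision) on every call, before negative estimates are clamped to
zero (clamp counts are kept in `n_negative`).

**Second-scan timing.** FPA1 places the second scan at the retrospective AIF
peak $t_{max}$ — the theoretical optimum, unknowable prospectively. FPA2 uses
only injection information: the temporal center of the bolus sits near

$$t_p = \tfrac{t_i}{2} + d,$$

with $t_i$ the injection duration (80 ml at 5 ml/s gives 16 s) and $d$ an
organ-dependent dispersion delay. `run_sweep()` evaluates $d = 0$ to $13.5$ s
in 1.5 s steps (timings t1–t10, i.e. $t_p$ from 8 to 21.5 s) and correlates
each FPA2 map against MSM across the cohort, pooling carcinoma and
parenchyma: once over subject-level circular-ROI means, once over all voxels
of the polygonal ROIs. The optimum range is the longest contiguous run of
timings with $r$ above both thresholds (0.90 for means, 0.70 voxelwise);
`optimum_delay_window()` converts its endpoints back through $t_p$ into the
recommended second-scan delay window after the trigger. For the dispersion
range 7.5–12.0 s this window is 15.5–20.0 s.

## The synthetic cohort

Patient data of this kind are not publicly available, so the generator in
`sample_cohort()` is the package's source of truth. What it emulates, and
the choices behind the defaults:

* **Protocol** (`acquisition_protocol()`): 34 frames every 1.5 s starting
  13 s after injection start; 80 ml at 5.0 ml/s; 120 HU trigger.
* **AIF** (`make_aif()`): gamma variate
  $b + A(t-t_0)^{\alpha}e^{-(t-t_0)/\beta}$ — the standard analytic bolus
  surrogate, differentiable with a closed-form peak at $t_0+\alpha\beta$.
  Defaults (baseline 45 HU, onset 13.5 s, $\alpha = 3$, $\beta = 2.5$ s, peak
  enhancement 300 HU) were chosen so that the absolute 120 HU trigger fires
  about 3 frames into the window and the AIF peaks near 21 s, inside the
  frame window, mimicking a bolus-tracked abdominal exam at 80 kVp. The peak
  height is flagged in the config file: weaken it and the trigger may never
  fire (subjects are then skipped with a warning, never silently dropped).
* **Tissue** (`simulate_tac()`): convolution of the AIF enhancement with a
  boxcar residue of mean transit time MTT (default 12 s), scaled by
  BF/6000. The boxcar makes the no-outflow regime explicit: before
  $t_0 + \mathrm{MTT}$ the TAC is exactly the cumulative AIF integral, so
  the two-scan estimate is exact there; after it, contrast genuinely leaves
  and FPA underestimates — shorter MTTs probe violation of the assumption.
* **Population**: per-subject BF from truncated normals — parenchyma
  106.8 ± 41.5, carcinoma 42.0 ± 24.8 ml/100 ml/min, floored at 5 (the floor
  keeps draws physiological; at these means it shifts the moments
  negligibly) — with per-subject AIF jitter (onset SD 0.75 s, peak SD
  40 HU). Sixteen subjects by default.
* **Noise**: additive i.i.d. Gaussian, 5 HU SD per voxel per frame — the
  scale of a soft-kernel 80 kVp reconstruction. No photon statistics, beam
  hardening, or motion; the noise model is there to exercise ROI averaging
  and voxelwise correlation degradation, nothing subtler.
* **Geometry** (`phantom_geometry()`): one 96 × 96 slice (nominal 1 mm
  pitch) with a circular aortic ROI and, per tissue, a polygonal whole-tissue
  ROI with a circular high-confidence ROI strictly inside it; areas are on
  the clinical order (≈80 voxels circular, ≈750/≈2300 polygonal). Regions of
  different tissues are disjoint by construction and validated.

All randomness descends from one seed: cohort-level draws use it directly and
each subject gets a derived rasterization seed, so cohorts are bit-reproducible.

## What passing tests do and do not show

The tests demonstrate internal correctness — estimator algebra, timing
logic, seeded reproducibility, parameter recovery within 5% on noise-free
subjects, and the qualitative cohort pattern (high FPA-vs-MSM correlation, a
contiguous high-correlation FPA2 band, carcinoma–parenchyma separation at
p < 0.0001). They do **not** show clinical performance: voxels within a
region share one true BF, there is no motion or partial voluming, and the
boxcar washout is cruder than real pancreatic kinetics. Three consequences
are worth stating plainly:

* **Timing sensitivity (COV) is exaggerated.** With MTT = 12 s the late
  sweep timings sit well into outflow, so FPA2 BF falls steeply with $d$ and
  the COV across timings is ≈40%, versus ≈10% reported for real pancreas. In
  the no-outflow regime (long MTT) the synthetic COV drops to the few-percent
  range and grows monotonically with voxel noise. Related: the zero-clamp
  interacts with near-zero raw estimates at late timings, so under short MTT
  *more* noise can *lower* the measured COV (clamping pulls noisy means up);
  the monotonicity property therefore only holds where no clamping occurs.
* **The synthetic optimum band sits earlier than a real one.** For the same
  reason, voxelwise correlation decays at late timings and the combined
  optimum range lands at small $d$; on real data with slow washout, later
  timings remain competitive.
* **Voxelwise MSM is noise-biased upward.** The max-over-windows slope
  statistic rides on the largest noise excursion; at 5 HU noise, window 3
  (the default) inflates voxel-map ROI means substantially. Correlations are
  insensitive to this near-uniform inflation, and ROI-level curves are barely
  affected, but absolute voxelwise MSM values at this noise level should be
  read with that bias in mind. A `fit = "gammafit"` mode (per-voxel
  gamma-variate smoothing before differentiation) is available and much
  slower; widening `slope_window` trades noise for peak-slope smoothing bias
  (window 3 keeps the noise-free discretization bias ≈2%, within the 5%
  recovery budget; window 5 already exceeds it at these AIF time scales).

## Numerical choices and edge cases

* Trigger comparison is strict (`> 120` HU) in absolute HU; the AIF peak and
  the FPA integral use enhancement above baseline by default, with an
  absolute-HU mode for sensitivity analysis. The AIF baseline is the mean of
  pre-trigger frames (first frame if none precede).
* $t_p$ between frames resolves to the nearest frame, earlier on ties; a
  target beyond the last frame raises a "window exceeded" error rather than
  truncating.
* Ties in the AIF maximum resolve to the earliest frame.
* Negative BF voxels are clamped to zero after the conservation check, and
  counted.
* Integrals are trapezoidal on the frame grid; no interpolation or
  resampling is performed anywhere in the estimators.
* Student's t-test is the classical equal-variance two-sided test; no
  multiple-testing correction is applied across the ten timings (raw
  p-values are reported).
* COV across timings is computed per subject then averaged (sensitivity of a
  patient's own value to timing), with the cohort-mean variant reported
  alongside; both are given for circular and polygonal ROIs.

## Dose accounting

`effective_dose()` multiplies a dose-length product by the abdominal
conversion factor 0.0153 mSv/(mGy·cm). The two-scan protocol's DLP defaults
to 2/34 of the dynamic protocol's (dose proportional to acquisition count;
bolus-monitoring dose excluded), and `percent_reduction(0.27, 4.64)` — the
reference per-patient effective doses of a two-scan versus a full dynamic
pancreatic acquisition at 80 kVp — rounds to the headline 94%.
`protocol_scan_time()` uses the package's own bookkeeping formulas (dynamic:
inter-frame span plus one acquisition; two-scan: monitoring lead plus
second-scan delay plus one acquisition) and makes no claim to reproduce
scanner-console timings exactly.

## Problem sizes

Default analyses use the 96 × 96 single-slice grid with 34 frames and 16
subjects; the test suite additionally uses a 48 × 48 scaled phantom for
cohort-level property checks. These sizes were chosen as the smallest that
keep every ROI on the clinical order of magnitude while making a full sweep
(16 subjects × 11 timings × MSM) a matter of seconds on one core.
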