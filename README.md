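# ctperf

Quantitative CT perfusion of the pancreas from dynamic contrast-enhanced
acquisitions, built around the question: *can two well-timed volume scans
replace a 34-volume dynamic series?* Full dynamic CT perfusion separates
pancreatic adenocarcinoma (low blood flow) from healthy parenchyma (high
blood flow) but costs several mSv per exam. First-pass analysis (FPA) needs
only a bolus-triggered scan pair, at roughly 1/17 of the dose — if the second
scan lands near the arterial peak.

The package provides, for researchers evaluating low-dose perfusion
protocols:

* **Estimators.** The maximum slope model (MSM) reference,
  `BF = 6000 · max(dTAC/dt) / (AIF_max · ρ_t)`, and the two-scan FPA map,
  `BF = 6000 · ΔHU / ∫ AIF_enh dt`, both voxelwise
  (`msm_map()`, `fpa_map()`), with bolus-tracking trigger detection
  (`find_tbase()`, 120 HU absolute) and second-scan selection at the AIF
  peak (FPA1) or by the temporal-center rule `t_p = t_i/2 + d` (FPA2,
  `compute_tp()`, `select_second_frame()`).
* **Timing optimization.** `run_sweep()` evaluates FPA2 over dispersion
  delays d = 0–13.5 s against MSM on a cohort (Pearson r on circular-ROI
  means and on polygonal-ROI voxels, tissues pooled; COV across timings;
  carcinoma-vs-parenchyma t-tests) and `optimum_delay_window()` converts the
  optimum d-range into a second-scan delay window after the trigger.
* **A synthetic dynamic-CT cohort** with known ground truth
  (`sample_cohort()`): gamma-variate AIFs, boxcar-residue tissue curves,
  clinical ROI layout, Gaussian HU noise, fully seeded — so every estimator
  is validated by parameter recovery instead of unavailable patient data.
* **Dose accounting** (`effective_dose()`, `percent_reduction()`,
  `dose_comparison()`): DLP × 0.0153 mSv/(mGy·cm) and protocol comparisons.

## Worked example

Generate a 16-subject cohort under the default protocol (34 frames / 1.5 s,
80 ml at 5 ml/s, trigger 120 HU) and sweep the second-scan timing:

```r
library(ctperf)
cohort <- sample_cohort(n_subjects = 16, seed = 1)
res <- run_sweep(cohort)
res
#> <sweep_result> 16 subjects (0 skipped), 10 FPA2 timings
#>    timing    d r_mean_rois r_voxelwise t_circ   p_circ p_voxel
#> 1    fpa1   NA       0.965       0.599  -5.38 7.97e-06       0
#> 2      t1  0.0       0.965       0.748  -5.67 3.54e-06       0
#> 3      t2  1.5       0.965       0.756  -5.66 3.66e-06       0
#> 4      t3  3.0       0.964       0.752  -5.63 3.89e-06       0
#> 5      t4  4.5       0.958       0.742  -5.67 3.48e-06       0
#> 6      t5  6.0       0.953       0.729  -5.72 3.09e-06       0
#> 7      t6  7.5       0.942       0.707  -5.86 2.07e-06       0
#> 8      t7  9.0       0.941       0.674  -5.64 3.84e-06       0
#> 9      t8 10.5       0.931       0.621  -5.85 2.10e-06       0
#> 10     t9 12.0       0.912       0.544  -6.24 7.06e-07       0
#> 11    t10 13.5       0.904       0.438  -5.92 1.75e-06       0
#> COV (per-subject mean, %): carcinoma 42.4, parenchyma 43.4
#> optimum timings: t1, t2, t3, t4, t5, t6 (d = 0..7.5 s)
optimum_delay_window(res, t_i = injection_duration(80, 5))
#> [1]  8.0 15.5
```

Reading this: every FPA2 timing correlates with the 34-volume MSM reference
at r > 0.90 on circular-ROI means (`r_mean_rois`), FPA1 — the theoretical
optimum with the second scan at the AIF peak — reaches r = 0.965, and
carcinoma vs parenchyma separates at p < 1e-5 at every timing (`p_circ`).
Voxelwise correlation (`r_voxelwise`) peaks at early delays and decays late,
where the synthetic tissue (boxcar washout, MTT 12 s) is already shedding
contrast; the contiguous run passing both thresholds (r > 0.90 means,
r > 0.70 voxelwise) is t1–t6, i.e. a second scan 8.0–15.5 s after the
trigger for this generator. The high COV (~42% across timings) is likewise a
deliberate property of the short-MTT synthetic washout — see the methods
vignette (`vignettes/ct-first-pass-perfusion.Rmd`) for what the phantom does
and does not emulate. With the dispersion-delay range 7.5–12.0 s appropriate
for pancreatic dispersion, the same rule gives the clinical recommendation:

```r
optimum_delay_window(list(optimum = list(d_range = c(7.5, 12))), t_i = 16)
#> [1] 15.5 20.0
```

Dose side, with a 303 mGy·cm dynamic DLP and the two-scan DLP at 2/34 of it:

```r
dose_comparison(dlp_dynamic = 303)
#>     label n_volumes    dlp effective_dose scan_time dose_reduction_pct time_reduction_pct
#> 1 dynamic        34 303.00         4.6359        50               0.00                  0
#> 2     fpa         2  17.82         0.2727        27              94.12                 46
```

The `analysis/` directory holds the full narrative pipeline as numbered
drivers — `01_simulate_cohort.R` (cohort to `scratch/`, ground truth to
`results/`), `02_perfusion_maps.R` (per-subject MSM/FPA1/FPA2 maps and ROI
statistics), `03_timing_sweep.R` (the sweep, tidy CSV/JSON outputs and
figures), `04_dose_report.R` — each runnable from the repository root after
installing the package.

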