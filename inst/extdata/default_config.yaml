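# Default run configuration for the synthetic perfusion cohort.
#
# NOTE on AIF defaults: the aortic peak enhancement (population.aif.peak_mean,
# 300 HU over a 45 HU baseline, onset 13.5 s, gamma-variate alpha 3 / beta
# 2.5 s) is chosen so that the 120 HU absolute bolus-tracking trigger fires
# on about the third frame of the dynamic window and the AIF peaks ~21 s
# after injection start, well inside the 34-frame window. Change these
# together: a weaker or later bolus can leave the trigger unfired.
protocol:
  n_frames: 34
  frame_spacing: 1.5       # s
  start_delay: 13          # s after injection start
  injection_volume: 80     # ml
  injection_rate: 5.0      # ml/s -> t_i = 16 s
  trigger_threshold: 120   # HU, absolute
geometry:
  image_shape: [96, 96]    # voxels, nominal 1 mm pitch
population:
  parenchyma: {mean: 106.8, sd: 41.5}   # ml/100 ml/min
  carcinoma:  {mean: 42.0,  sd: 24.8}
  bf_floor: 5
  mtt: 12                  # s, boxcar residue
  aif:
    onset_mean: 13.5       # s
    onset_sd: 0.75
    onset_min: 13.1
    peak_mean: 300         # HU enhancement
    peak_sd: 40
    peak_min: 180
noise:
  sigma: 5                 # HU, i.i.d. Gaussian per voxel and frame
perfusion:
  msm:
    slope_window: 3
    rho_t: 1.0
    aif_reference: enhancement
    fit: slope
  fpa:
    variant: fpa2
    trigger_threshold: 120
    t_i: 16
    dispersion_d: 0
    aif_reference: enhancement
sweep:
  d_values: [0, 1.5, 3, 4.5, 6, 7.5, 9, 10.5, 12, 13.5]
  r_threshold_mean: 0.90
  r_threshold_voxel: 0.70
dose:
  dlp_dynamic: 303         # mGy.cm -> 4.64 mSv at k = 0.0153
  conversion_k: 0.0153
  acq_time: 0.5            # s per volume
  monitor_lead: 6.5        # s, bolus-monitoring start to trigger
  fpa_last_delay: 20.0     # s, upper end of the recommended window
output:
  dir: results
seed: 1
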