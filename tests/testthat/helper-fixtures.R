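# Shared fixtures: a scaled-down phantom for fast cohort tests, and a
# convenience builder for single noise-free subjects.

small_geometry <- function() {
  phantom_geometry(
    image_shape = c(48, 48),
    aorta = list(center = c(9, 10), radius = 2.5),
    carcinoma = list(
      vertices = regular_polygon(c(15, 24), 8, 8),
      circ_center = c(15, 24), circ_radius = 2.5
    ),
    parenchyma = list(
      vertices = rbind(c(24, 15), c(35, 11), c(45, 17),
                       c(45, 35), c(32, 39), c(24, 30)),
      circ_center = c(35, 25), circ_radius = 2.5
    )
  )
}

make_subject <- function(bf_par = 106.8, bf_car = 42.0, mtt = 20,
                         noise_sigma = 0, seed = 7,
                         geometry = phantom_geometry(),
                         protocol = acquisition_protocol(),
                         aif = aif_params()) {
  rasterize_subject(
    protocol, geometry, aif,
    tissue_specs = list(
      parenchyma = tissue_spec("parenchyma", bf_par, mtt = mtt),
      carcinoma = tissue_spec("carcinoma", bf_car, mtt = mtt)
    ),
    noise_sigma = noise_sigma, seed = seed
  )
}

# pipeline AIF: extracted from the aorta mask with its baseline taken from
# the pre-trigger frames, as run_sweep does
pipeline_aif <- function(subject, threshold = 120) {
  aif0 <- extract_tac(subject$series, subject$masks$aorta)
  extract_tac(subject$series, subject$masks$aorta,
              tbase = find_tbase(aif0, threshold))
}
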