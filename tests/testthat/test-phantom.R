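test_that("noise-free voxels reproduce their region's simulated TAC exactly", {
  subj <- make_subject(noise_sigma = 0, mtt = 20)
  tac <- simulate_tac(subj$aif_true, tissue_spec("parenchyma", 106.8, mtt = 20))
  vox <- which(subj$masks$parenchyma_poly$mask, arr.ind = TRUE)
  for (k in c(1, nrow(vox))) {
    expect_equal(subj$series$voxels[, vox[k, 1], vox[k, 2]], tac$values)
  }
  # aorta voxels carry the AIF itself
  avox <- which(subj$masks$aorta$mask, arr.ind = TRUE)[1, ]
  expect_equal(subj$series$voxels[, avox[1], avox[2]], subj$aif_true$values)
})

test_that("rasterization is bit-identical under a fixed seed", {
  s1 <- make_subject(noise_sigma = 5, seed = 123, geometry = small_geometry())
  s2 <- make_subject(noise_sigma = 5, seed = 123, geometry = small_geometry())
  expect_identical(s1$series$voxels, s2$series$voxels)
  s3 <- make_subject(noise_sigma = 5, seed = 124, geometry = small_geometry())
  expect_false(identical(s1$series$voxels, s3$series$voxels))
})

test_that("aorta ROI mean stays within 3 standard errors of the noise-free AIF", {
  subj <- make_subject(noise_sigma = 5, seed = 99)  # default aorta: 81 voxels
  n_vox <- sum(subj$masks$aorta$mask)
  expect_gte(n_vox, 100 * 0.8)  # order 100 voxels as the SEM argument assumes
  aif_meas <- extract_tac(subj$series, subj$masks$aorta)
  expect_true(all(abs(aif_meas$values - subj$aif_true$values) <=
                    3 * 5 / sqrt(n_vox)))
})

test_that("phantom geometry enforces disjoint regions and ROI nesting", {
  g <- phantom_geometry()
  m <- g$masks
  expect_false(any(m$aorta & (m$carcinoma_poly | m$parenchyma_poly)))
  expect_false(any(m$carcinoma_poly & m$parenchyma_poly))
  expect_true(all(m$carcinoma_poly[m$carcinoma_circ]))
  expect_true(all(m$parenchyma_poly[m$parenchyma_circ]))
  # overlapping tissues are rejected
  expect_error(
    phantom_geometry(carcinoma = list(
      vertices = regular_polygon(c(60, 50), 16, 8),
      circ_center = c(60, 50), circ_radius = 5
    )),
    "overlap"
  )
  # a circular ROI escaping its polygon is rejected
  expect_error(
    phantom_geometry(carcinoma = list(
      vertices = regular_polygon(c(30, 48), 16, 8),
      circ_center = c(14, 48), circ_radius = 5
    )),
    "inside"
  )
})

test_that("cohort sampling is reproducible and matches its population", {
  expect_length(sample_cohort(1, geometry = small_geometry(), seed = 5), 1)
  expect_error(sample_cohort(0), "n_subjects")

  c1 <- sample_cohort(3, geometry = small_geometry(), seed = 8)
  c2 <- sample_cohort(3, geometry = small_geometry(), seed = 8)
  expect_identical(cohort_ground_truth(c1), cohort_ground_truth(c2))
  expect_identical(c1[[2]]$series$voxels, c2[[2]]$series$voxels)

  # CLT on the parenchyma generator: n = 200 draws of N(106.8, 41.5) floored
  # at 5 (truncation shifts the mean by < 0.01 at this distance)
  co <- sample_cohort(200, geometry = small_geometry(), noise_sigma = 0, seed = 21)
  gt <- cohort_ground_truth(co)
  m <- mean(gt$bf_true[gt$label == "parenchyma"])
  expect_lt(abs(m - 106.8), 3 * 41.5 / sqrt(200))
})

test_that("rasterize_subject validates noise and seed arguments", {
  g <- small_geometry()
  ts <- list(parenchyma = tissue_spec("parenchyma", 100),
             carcinoma = tissue_spec("carcinoma", 40))
  expect_error(rasterize_subject(acquisition_protocol(), g, aif_params(), ts,
                                 noise_sigma = -1, seed = 1), "noise_sigma")
  expect_error(rasterize_subject(acquisition_protocol(), g, aif_params(), ts),
               "seed")
})
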