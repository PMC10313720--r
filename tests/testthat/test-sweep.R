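test_that("sweep result has one record per timing plus the FPA1 reference", {
  co <- sample_cohort(3, geometry = small_geometry(), seed = 14)
  res <- run_sweep(co)
  expect_s3_class(res, "sweep_result")
  expect_identical(res$records$timing, c("fpa1", paste0("t", 1:10)))
  expect_identical(res$records$d[-1], seq(0, 13.5, by = 1.5))
  expect_true(all(res$records$r_mean_rois >= -1 & res$records$r_mean_rois <= 1))
  expect_true(all(res$cov$carcinoma >= 0) && all(res$cov$parenchyma >= 0))
  # bf_table covers every timing x tissue x ROI kind plus the MSM reference
  expect_identical(nrow(res$bf_table), (11L + 1L) * 2L * 2L)
})

test_that("noise-free no-outflow cohorts correlate with MSM at r ~ 1 everywhere", {
  co <- sample_cohort(5, population = default_population(mtt = 40),
                      geometry = small_geometry(), noise_sigma = 0, seed = 3)
  res <- run_sweep(co)
  expect_true(all(res$records$r_mean_rois > 0.999))
  expect_true(all(res$records$r_voxelwise > 0.999))
  # with every timing above both thresholds the optimum spans the whole sweep
  expect_identical(res$optimum$labels, paste0("t", 1:10))
  expect_equal(res$optimum$d_range, c(0, 13.5))
})

test_that("a single-subject cohort is flagged degenerate for mean-ROI correlation", {
  co <- sample_cohort(1, geometry = small_geometry(), seed = 6)
  res <- run_sweep(co)
  expect_true(res$degenerate_mean_r)
  expect_true(all(is.na(res$records$r_mean_rois)))
  expect_true(all(is.finite(res$records$r_voxelwise)))
})

test_that("correlations are invariant to subject ordering", {
  co <- sample_cohort(4, geometry = small_geometry(), seed = 9)
  r1 <- run_sweep(co)
  r2 <- run_sweep(co[c(3, 1, 4, 2)])
  expect_equal(r2$records$r_mean_rois, r1$records$r_mean_rois)
  expect_equal(r2$records$r_voxelwise, r1$records$r_voxelwise)
})

test_that("COV weakly increases with voxel noise in the no-outflow regime", {
  pop <- default_population(mtt = 40)
  cov_at <- function(sigma) {
    co <- sample_cohort(6, population = pop, geometry = small_geometry(),
                        noise_sigma = sigma, seed = 11)
    r <- run_sweep(co)
    c(r$cov$carcinoma[["per_subject_mean"]], r$cov$parenchyma[["per_subject_mean"]])
  }
  c0 <- cov_at(0); c5 <- cov_at(5); c10 <- cov_at(10)
  expect_true(all(c0 <= c5))
  expect_true(all(c5 <= c10))
})

test_that("subjects without all masks or with no trigger are handled explicitly", {
  co <- sample_cohort(2, geometry = small_geometry(), seed = 4)
  broken <- co
  broken[[1]]$masks$aorta <- NULL
  expect_error(run_sweep(broken), "missing masks: aorta")

  # a bolus too weak to cross 120 HU is skipped with a warning
  weak <- make_subject(geometry = small_geometry(), seed = 10,
                       aif = aif_params(peak_enhancement = 50))
  expect_warning(res <- run_sweep(c(co, list(weak))), "trigger never fired")
  expect_identical(res$skipped, 3L)
  expect_identical(res$n_subjects, 2L)
})

test_that("optimum delay window translates d into seconds after the trigger", {
  stub <- list(optimum = list(d_range = c(7.5, 12.0)))
  expect_equal(optimum_delay_window(stub, t_i = 16), c(15.5, 20.0))
  expect_equal(optimum_delay_window(list(optimum = list(d_range = c(0, 0))), 16),
               c(8, 8))
  expect_equal(optimum_delay_window(list(optimum = list(d_range = c(4.5, 4.5))), 16),
               c(12.5, 12.5))
  expect_error(optimum_delay_window(list(optimum = list(d_range = c(NA_real_, NA_real_))), 16),
               "empty optimum range")
})
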