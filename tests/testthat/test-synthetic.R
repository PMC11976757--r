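test_that("noiseless signal model produces the exact planted step response", {
  p <- co2_protocol(step_amplitude = 10)
  ph <- small_phantom(noise_sd = 0,
                      cvr_levels = c(healthy = 0.2, lesion = 0.04,
                                     steal = -0.1),
                      baseline_signal = 1000)
  b <- synthesize_subject(ph, p, seed = 1)
  ep <- protocol_epochs(p)
  vox <- which(b$cvr_truth == 0.2, arr.ind = TRUE)[1, ]
  s <- b$bold[vox[1], vox[2], vox[3], ]
  expect_equal(mean(s[ep$plateau]) - mean(s[ep$baseline]), 20)
  # paradoxical (negative) reactivity drops the plateau symmetrically
  voxn <- which(b$cvr_truth == -0.1, arr.ind = TRUE)[1, ]
  sn <- b$bold[voxn[1], voxn[2], voxn[3], ]
  expect_equal(mean(sn[ep$plateau]), 990)
  expect_equal(mean(sn[ep$baseline]), 1000)
})

test_that("zero reactivity gives a constant noiseless series at baseline", {
  ph <- small_phantom(noise_sd = 0,
                      cvr_levels = c(healthy = 0, lesion = 0, steal = -0.1))
  b <- synthesize_subject(ph, co2_protocol(), seed = 1)
  vox <- which(b$cvr_truth == 0, arr.ind = TRUE)[1, ]
  expect_true(all(b$bold[vox[1], vox[2], vox[3], ] ==
                    ph$baseline_signal))
})

test_that("the same seed reproduces a subject and a cohort bit-identically", {
  ph <- small_phantom(noise_sd = 10)
  b1 <- synthesize_subject(ph, co2_protocol(), seed = 42)
  b2 <- synthesize_subject(ph, co2_protocol(), seed = 42)
  expect_identical(b1$bold, b2$bold)
  expect_identical(b1$motion, b2$motion)
  sp <- cohort_spec(n_subjects = 50, seed = 9)
  expect_identical(synthesize_cohort(sp)$table, synthesize_cohort(sp)$table)
})

test_that("phantom geometry outside the grid is rejected", {
  expect_error(phantom_spec(grid_shape = c(16, 16, 8),
                            lesion_center = c(15, 8, 4),
                            lesion_radii = c(4, 4, 2)),
               "outside the grid")
  expect_error(small_phantom(cvr_levels = c(healthy = 0.15, lesion = 0.04,
                                            steal = 0.05)),
               "negative")
})

test_that("rank coupling hits the target lesion/steal association", {
  t0 <- synthesize_cohort(cohort_spec(n_subjects = 2000,
                                      steal_outside_association = 0,
                                      seed = 11))$table
  expect_lt(abs(cor(t0$lesion_ml, t0$steal_outside_ml,
                    method = "spearman")), 0.06)
  t1 <- synthesize_cohort(cohort_spec(n_subjects = 2000,
                                      steal_outside_association = 0.77,
                                      seed = 12))$table
  expect_lt(abs(cor(t1$lesion_ml, t1$steal_outside_ml,
                    method = "spearman") - 0.77), 0.03)
})

test_that("null outcome slopes reproduce the cutpoint-implied base rates", {
  om <- list(beta = c(steal_outside_ml = 0, lesion_ml = 0, age = 0,
                      nihss_admission = 0),
             categories = 0:5,
             base_probs = c(0.3, 0.25, 0.2, 0.1, 0.1, 0.05))
  tab <- synthesize_cohort(cohort_spec(n_subjects = 4000,
                                       outcome_model = om,
                                       seed = 13))$table
  freq <- tabulate(tab$nihss_discharge + 1L, 6L) / 4000
  expect_lt(max(abs(freq - om$base_probs)), 0.025)
})

test_that("realized lesion-volume median converges to the law's median", {
  tab <- synthesize_cohort(cohort_spec(n_subjects = 5000, seed = 14))$table
  med_law <- exp(log(26.3))
  expect_lt(abs(median(tab$lesion_ml) - med_law) / med_law, 0.05)
})
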