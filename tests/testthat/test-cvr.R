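test_that("the regressor is the delayed, baseline-centered stimulus", {
  p <- co2_protocol()
  tr <- petco2_trace(p)
  r0 <- build_regressor(tr, p, delay = 0)
  ep <- protocol_epochs(p)
  expect_true(all(r0[ep$baseline] == 0))
  expect_true(all(r0[ep$plateau] == 10))
  # one-TR delay equals a one-frame shift
  r1 <- build_regressor(tr, p, delay = p$tr)
  shifted <- c(tr[1], tr[-length(tr)])
  expect_equal(r1, shifted - mean(shifted[ep$baseline]))
  expect_true(all(build_regressor(rep(40, 150), p) == 0))
  expect_error(build_regressor(tr, p, delay = 100), "baseline")
})

test_that("noiseless phantoms are inverted exactly, signs preserved", {
  ph <- small_phantom(noise_sd = 0)
  b <- synthesize_subject(ph, co2_protocol(), seed = 1)
  cvr <- compute_cvr(b$bold, b$petco2, b$protocol, b$grid,
                     brain_mask = b$brain_mask)
  expect_lt(max(abs(cvr$values - b$cvr_truth), na.rm = TRUE), 1e-6)
  expect_true(all(cvr$values[b$steal_truth] < 0))
  expect_true(all(is.na(cvr$values[!b$brain_mask])))
})

test_that("a planted hemodynamic delay is absorbed by the matching regressor", {
  ph <- small_phantom(noise_sd = 0, hemodynamic_delay = 6)
  b <- synthesize_subject(ph, co2_protocol(), seed = 2)
  cvr <- compute_cvr(b$bold, b$petco2, b$protocol, b$grid,
                     brain_mask = b$brain_mask, delay = 6)
  expect_lt(max(abs(cvr$values - b$cvr_truth), na.rm = TRUE), 1e-6)
})

test_that("regression estimator equals the epoch-ratio closed form on ideal steps", {
  ph <- small_phantom(noise_sd = 0)
  p <- co2_protocol()
  b <- synthesize_subject(ph, p, seed = 1)
  cvr <- compute_cvr(b$bold, b$petco2, b$protocol, b$grid,
                     brain_mask = b$brain_mask)
  ep <- protocol_epochs(p)
  sig <- matrix(b$bold, prod(b$grid$shape), length(b$petco2))
  m0 <- rowMeans(sig[, ep$baseline])
  m1 <- rowMeans(sig[, ep$plateau])
  ratio <- 100 * (m1 - m0) / (p$step_amplitude * m0)
  inb <- as.vector(b$brain_mask)
  expect_lt(max(abs(as.vector(cvr$values)[inb] - ratio[inb])), 1e-9)
})

test_that("CVR is a ratio: invariant to signal rescaling and step doubling", {
  ph <- small_phantom(noise_sd = 0)
  b <- synthesize_subject(ph, co2_protocol(), seed = 1)
  cvr <- compute_cvr(b$bold, b$petco2, b$protocol, b$grid)
  cvr_scaled <- compute_cvr(b$bold * 7.3, b$petco2, b$protocol, b$grid)
  expect_equal(cvr_scaled$values, cvr$values, tolerance = 1e-12)
  p2 <- co2_protocol(step_amplitude = 20)
  b2 <- synthesize_subject(ph, p2, seed = 1)
  cvr2 <- compute_cvr(b2$bold, b2$petco2, p2, b2$grid)
  expect_equal(cvr2$values, cvr$values, tolerance = 1e-9)
})

test_that("estimates are unbiased at realistic noise", {
  ph <- small_phantom(noise_sd = 10,   # 1% of baseline signal
                      cvr_levels = c(healthy = 0.10, lesion = 0.04,
                                     steal = -0.10))
  devs <- vapply(1:20, function(s) {
    b <- synthesize_subject(ph, co2_protocol(), seed = 100 + s)
    cvr <- compute_cvr(b$bold, b$petco2, b$protocol, b$grid,
                       brain_mask = b$brain_mask)
    sel <- which(b$cvr_truth == 0.10)
    mean(cvr$values[sel[1:500]]) - 0.10
  }, numeric(1))
  expect_lt(max(abs(devs)), 0.005)
})

test_that("degenerate stimuli and baselines are flagged", {
  ph <- small_phantom(noise_sd = 0)
  p0 <- co2_protocol(step_amplitude = 0)
  b <- synthesize_subject(ph, p0, seed = 1)
  expect_error(compute_cvr(b$bold, b$petco2, p0, b$grid), "stimulus error")
  b2 <- synthesize_subject(ph, co2_protocol(), seed = 1)
  expect_error(compute_cvr(b2$bold, b2$petco2[-1], b2$protocol, b2$grid),
               "alignment error")
})

test_that("Z-scoring standardizes against the atlas voxelwise", {
  ph <- small_phantom(noise_sd = 0, atlas_mean = 0.15, atlas_sd = 0.05)
  b <- synthesize_subject(ph, co2_protocol(), seed = 1)
  cvr <- compute_cvr(b$bold, b$petco2, b$protocol, b$grid,
                     brain_mask = b$brain_mask)
  z <- zscore_map(cvr, b$atlas_ref)
  healthy <- b$cvr_truth == 0.15 & !is.na(b$cvr_truth)
  expect_lt(max(abs(z$values[healthy])), 1e-6)           # CVR == atlas mean
  steal <- b$steal_truth
  expect_equal(unique(round(z$values[steal], 6)), -5)    # (-0.10-0.15)/0.05
  # impaired-but-positive tissue: CVR -0.05 against mean 0.15, sd 0.05
  ph4 <- small_phantom(noise_sd = 0, atlas_mean = 0.15, atlas_sd = 0.05,
                       cvr_levels = c(healthy = 0.15, lesion = -0.05,
                                      steal = -0.10))
  b4 <- synthesize_subject(ph4, co2_protocol(), seed = 1)
  cvr4 <- compute_cvr(b4$bold, b4$petco2, b4$protocol, b4$grid,
                      brain_mask = b4$brain_mask)
  z4 <- zscore_map(cvr4, b4$atlas_ref)
  lesion_only <- b4$lesion_mask & !b4$steal_truth
  expect_equal(unique(round(z4$values[lesion_only], 6)), -4)
})
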