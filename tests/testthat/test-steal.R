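analyzed_phantom <- function(ph, seed = 1) {
  b <- synthesize_subject(ph, co2_protocol(), seed = seed)
  cvr <- compute_cvr(b$bold, b$petco2, b$protocol, b$grid,
                     brain_mask = b$brain_mask)
  list(bundle = b, cvr = cvr, z = zscore_map(cvr, b$atlas_ref))
}

test_that("steal requires both a negative response and atlas-atypical deviation", {
  # all-positive CVR -> empty mask regardless of Z (steal region placed
  # outside the lesion with an "inside" clip, so no voxel is negative)
  a <- analyzed_phantom(small_phantom(
    noise_sd = 0, cvr_levels = c(healthy = 0.15, lesion = 0.01,
                                 steal = -0.1),
    steal_regions = list(list(center = c(4, 4, 2), radii = c(1, 1, 1),
                              where = "inside"))))
  expect_true(all(a$cvr$values > 0, na.rm = TRUE))
  expect_equal(sum(detect_steal(a$cvr, a$z, 1e-9)$values), 0)

  # negative voxel kept at Z -3 but dropped at Z -1 (atlas SD widened)
  ph_in <- small_phantom(noise_sd = 0, atlas_mean = 0.05, atlas_sd = 0.05)
  a_in <- analyzed_phantom(ph_in)       # steal CVR -0.1 -> Z = -3
  m_in <- detect_steal(a_in$cvr, a_in$z, z_threshold = 2)
  expect_true(all(m_in$values[a_in$bundle$steal_truth]))
  ph_out <- small_phantom(noise_sd = 0, atlas_mean = 0.05, atlas_sd = 0.15)
  a_out <- analyzed_phantom(ph_out)     # same CVR -> Z = -1
  m_out <- detect_steal(a_out$cvr, a_out$z, z_threshold = 2)
  expect_equal(sum(m_out$values), 0)
})

test_that("noiseless phantoms recover the planted steal geometry exactly", {
  a <- analyzed_phantom(small_phantom(noise_sd = 0))
  m_perm <- detect_steal(a$cvr, a$z, z_threshold = 1e-9)  # permissive
  expect_identical(m_perm$values, a$bundle$steal_truth)
  m_def <- detect_steal(a$cvr, a$z, z_threshold = 2)
  expect_identical(m_def$values, a$bundle$steal_truth)
})

test_that("the mask is monotone and decomposable in the Z threshold", {
  a <- analyzed_phantom(small_phantom(noise_sd = 15), seed = 7)
  th <- c(0.5, 1, 2, 3, 5)
  masks <- lapply(th, function(t) detect_steal(a$cvr, a$z, t)$values)
  for (i in seq_along(th)[-1])
    expect_true(all(masks[[i]] <= masks[[i - 1]]))  # raising t never adds
  permissive <- detect_steal(a$cvr, a$z, 1e-9)$values
  for (i in seq_along(th)) {
    inter <- permissive & !is.na(a$z$values) & a$z$values <= -th[i]
    expect_identical(masks[[i]], inter)
  }
})

test_that("cluster cleaning follows 26-connectivity", {
  grid <- volume_grid(c(6, 6, 4))
  base <- array(FALSE, c(6, 6, 4))
  mk <- function(vals) structure(list(values = vals, grid = grid,
                                      criterion = list(cvr_below = 0,
                                                       z_threshold = 2)),
                                 class = "steal_mask")
  solo <- base; solo[3, 3, 2] <- TRUE
  expect_identical(clean_mask(mk(solo), 0)$values, solo)     # filter off
  expect_equal(sum(clean_mask(mk(solo), 2)$values), 0)       # isolated gone
  pair <- base; pair[3, 3, 2] <- TRUE; pair[4, 4, 3] <- TRUE # diagonal touch
  expect_identical(clean_mask(mk(pair), 2)$values, pair)
})

test_that("component labelling agrees with an independent graph oracle", {
  skip_if_not_installed("igraph")
  set.seed(77)
  for (rep in 1:5) {
    m <- array(runif(8 * 8 * 4) < 0.3, c(8, 8, 4))
    lab <- cvrsteal:::label_components(m)
    idx <- which(m)
    coords <- arrayInd(idx, dim(m))
    # oracle: graph over true voxels, edges at Chebyshev distance 1
    d <- as.matrix(dist(coords, method = "maximum"))
    g <- igraph::graph_from_adjacency_matrix(d <= 1, mode = "undirected",
                                             diag = FALSE)
    oracle <- igraph::components(g)$membership
    # same partition: labels must be a relabelling of each other
    expect_equal(length(unique(oracle)), max(lab))
    expect_true(all(tapply(oracle, lab[idx],
                           function(v) length(unique(v))) == 1))
    expect_true(all(tapply(lab[idx], oracle,
                           function(v) length(unique(v))) == 1))
  }
})
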