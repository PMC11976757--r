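# Shared fixtures and small oracles, all built in code.

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# 16x16x8 phantom: fast, with all tissue classes present
small_phantom <- function(noise_sd = 0, cvr_levels = c(healthy = 0.15,
                                                       lesion = 0.04,
                                                       steal = -0.10),
                          steal_regions = list(
                            list(center = c(12, 8, 4),
                                 radii = c(1.8, 2, 1.5), where = "inside"),
                            list(center = c(12, 11, 4),
                                 radii = c(2, 2, 1.5), where = "outside")),
                          ...) {
  phantom_spec(grid_shape = c(16L, 16L, 8L), voxel_size = c(3, 3, 3),
               lesion_center = c(12, 8, 4), lesion_radii = c(2.5, 3, 2),
               steal_regions = steal_regions,
               cvr_levels = cvr_levels, noise_sd = noise_sd, ...)
}

# minimal phantom for bulk cohort tests where masks are irrelevant
tiny_phantom <- function(...) {
  phantom_spec(grid_shape = c(8L, 8L, 4L), voxel_size = c(3, 3, 3),
               lesion_center = c(6, 4, 2), lesion_radii = c(1.5, 1.5, 1),
               steal_regions = list(list(center = c(6, 4, 2),
                                         radii = c(1, 1, 1),
                                         where = "inside")),
               ...)
}

# independent midrank oracle: counting definition, no calls to rank()
midrank_oracle <- function(v)
  vapply(v, function(a) sum(v < a) + (sum(v == a) + 1) / 2, numeric(1))

# independent Pearson correlation from raw sums
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
}

# simulate from a proportional-odds model with cumulative logits
# P(Y <= j) = plogis(alpha_j - x %*% beta); returns integer categories 1..J
sim_po_outcome <- function(X, beta, alpha) {
  eta <- drop(as.matrix(X) %*% beta)
  latent <- eta + rlogis(nrow(as.matrix(X)))
  findInterval(latent, alpha) + 1L
}
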