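#' Vascular territory labels used by the synthetic atlas
#'
#' Integer labels for the six hemispheric territories (anterior, middle and
#' posterior cerebral artery on each side). Label 0 is background/outside
#' brain.
#'
#' @return Data frame with columns `label`, `territory`, `hemisphere`.
#' @export
territory_labels <- function() {
  data.frame(label = 1:6,
             territory = rep(c("ACA", "MCA", "PCA"), 2L),
             hemisphere = rep(c("left", "right"), each = 3L),
             stringsAsFactors = FALSE)
}

#' Specification of a single synthetic subject (phantom)
#'
#' Defines the geometry and signal model of one digital phantom: an
#' ellipsoidal "brain" partitioned into six vascular territories, a DWI-like
#' infarct lesion, one or more steal regions (tissue with negative CVR),
#' planted reactivity per tissue class, and the BOLD signal/noise model.
#' Reactivity levels are in %-BOLD-signal-change per mmHg CO2; the defaults
#' sit in the range typically reported for grey matter (healthy ~0.15,
#' severely impaired infarct core ~0.04, steal tissue negative).
#'
#' @param grid_shape,voxel_size Voxel grid (see [volume_grid()]). Default
#'   32x32x16 voxels at 3 mm isotropic.
#' @param lesion_center,lesion_radii Ellipsoid of the infarct lesion, voxel
#'   units (1-based). Must lie inside the grid.
#' @param steal_regions List of steal-region specs, each a list with
#'   `center`, `radii` and `where` ("inside" clips the region to the lesion,
#'   "outside" subtracts the lesion).
#' @param cvr_levels Named vector with planted CVR for classes `healthy`,
#'   `lesion` and `steal` (%/mmHg); the steal level must be negative.
#' @param baseline_signal Baseline BOLD intensity (arbitrary units).
#' @param noise_sd SD of additive white Gaussian noise (same units).
#' @param hemodynamic_delay Lag (s) between the PetCO2 trace and the BOLD
#'   response; applied as a nearest-frame shift.
#' @param motion Per-frame head motion model: a random walk with Gaussian
#'   increments of SD `step_sd_trans` (mm) on the three translations and
#'   `step_sd_rot` (radians) on the three rotations.
#' @param atlas_mean,atlas_sd Healthy-reference CVR atlas values (mean and
#'   SD maps are constant at these values inside the brain); `atlas_sd > 0`.
#' @param affected_side Hemisphere of the stroke, `"left"` or `"right"`.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 16L),
                         voxel_size = c(3, 3, 3),
                         lesion_center = c(24, 16, 8),
                         lesion_radii = c(5, 6, 4),
                         steal_regions = list(
                           list(center = c(24, 16, 8), radii = c(4, 4, 3),
                                where = "inside"),
                           list(center = c(24, 23, 8), radii = c(5, 5, 4),
                                where = "outside")),
                         cvr_levels = c(healthy = 0.15, lesion = 0.04,
                                        steal = -0.10),
                         baseline_signal = 1000, noise_sd = 10,
                         hemodynamic_delay = 0,
                         motion = list(step_sd_trans = 0.02,
                                       step_sd_rot = 2e-4),
                         atlas_mean = 0.15, atlas_sd = 0.05,
                         affected_side = c("right", "left")) {
  affected_side <- match.arg(affected_side)
  grid <- volume_grid(grid_shape, voxel_size)
  check_geom <- function(center, radii, what) {
    if (any(center - radii < 0.5) || any(center + radii > grid$shape + 0.5))
      stop("invalid phantom: ", what, " extends outside the grid",
           call. = FALSE)
  }
  check_geom(lesion_center, lesion_radii, "lesion")
  for (sr in steal_regions) {
    if (!all(c("center", "radii", "where") %in% names(sr)) ||
        !sr$where %in% c("inside", "outside"))
      stop("invalid phantom: each steal region needs center, radii and where",
           call. = FALSE)
    check_geom(sr$center, sr$radii, "steal region")
  }
  if (!all(c("healthy", "lesion", "steal") %in% names(cvr_levels)))
    stop("cvr_levels must name healthy, lesion and steal classes",
         call. = FALSE)
  if (cvr_levels[["steal"]] >= 0)
    stop("invalid phantom: steal-class CVR must be negative", call. = FALSE)
  if (atlas_sd <= 0)
    stop("invalid phantom: atlas_sd must be > 0", call. = FALSE)
  stopifnot(baseline_signal > 0, noise_sd >= 0, hemodynamic_delay >= 0)
  structure(list(grid = grid, lesion_center = lesion_center,
                 lesion_radii = lesion_radii, steal_regions = steal_regions,
                 cvr_levels = cvr_levels, baseline_signal = baseline_signal,
                 noise_sd = noise_sd, hemodynamic_delay = hemodynamic_delay,
                 motion = motion, atlas_mean = atlas_mean,
                 atlas_sd = atlas_sd, affected_side = affected_side),
            class = "phantom_spec")
}

# Brain = large ellipsoid; hemispheres split on x; ACA/MCA/PCA as anterior/
# middle/posterior thirds of y within the brain. Returns label array (0 = out).
build_territories <- function(grid) {
  shp <- grid$shape
  brain <- ellipsoid_mask(shp, (shp + 1) / 2, 0.48 * shp)
  lab <- array(0L, shp)
  x <- slice.index(lab, 1)
  y <- slice.index(lab, 2)
  right <- x > shp[1] / 2
  band <- cut(y, breaks = c(0, shp[2] / 3, 2 * shp[2] / 3, shp[2]),
              labels = FALSE)
  lab[] <- ifelse(brain, band + 3L * right, 0L)
  lab
}

phantom_masks <- function(spec) {
  shp <- spec$grid$shape
  territories <- build_territories(spec$grid)
  brain <- territories > 0L
  lesion <- ellipsoid_mask(shp, spec$lesion_center, spec$lesion_radii) & brain
  steal <- array(FALSE, shp)
  for (sr in spec$steal_regions) {
    reg <- ellipsoid_mask(shp, sr$center, sr$radii) & brain
    reg <- if (sr$where == "inside") reg & lesion else reg & !lesion
    steal <- steal | reg
  }
  cvr <- array(NA_real_, shp)
  cvr[brain] <- spec$cvr_levels[["healthy"]]
  cvr[lesion] <- spec$cvr_levels[["lesion"]]
  cvr[steal] <- spec$cvr_levels[["steal"]]
  list(brain = brain, lesion = lesion, steal = steal,
       territories = territories, cvr = cvr)
}

#' Synthesize one subject's acquisition from a phantom
#'
#' Generates a 4D BOLD series following the linear reactivity model
#' `S(v, t) = B * (1 + CVR(v)/100 * (PetCO2(t - delay) - resting)) + noise`,
#' together with every ground-truth map the downstream pipeline consumes:
#' the planted CVR field, lesion and steal masks, territory atlas,
#' healthy-reference atlas, a motion trace and the PetCO2 trace. Voxels
#' outside the brain carry zero signal.
#'
#' @param spec A [phantom_spec()].
#' @param protocol A [co2_protocol()].
#' @param seed Integer seed; the same seed reproduces the subject
#'   bit-identically.
#' @param subject_id Identifier stored in the bundle.
#' @return Object of class `subject_bundle`: a list with elements `bold`
#'   (4D array), `petco2`, `motion` (frames x 6: translations mm then
#'   rotations rad), `protocol`, `grid`, `brain_mask`, `lesion_mask`,
#'   `steal_truth`, `cvr_truth`, `territories`, `atlas_ref`, `clinical`,
#'   `subject_id`.
#' @export
synthesize_subject <- function(spec, protocol = co2_protocol(), seed = NULL,
                               subject_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"), inherits(protocol, "co2_protocol"))
  with_seed(seed, {
    m <- phantom_masks(spec)
    pet <- petco2_trace(protocol)
    n <- length(pet)
    lag <- as.integer(round(spec$hemodynamic_delay / protocol$tr))
    if (lag >= n)
      stop("hemodynamic delay exceeds the series duration", call. = FALSE)
    pet_eff <- if (lag > 0) c(rep(pet[1], lag), pet[seq_len(n - lag)]) else pet
    dpet <- pet_eff - protocol$resting_petco2

    cvr_vec <- ifelse(is.na(m$cvr), 0, m$cvr)
    base <- ifelse(m$brain, spec$baseline_signal, 0)
    nv <- prod(spec$grid$shape)
    # voxels x frames signal matrix
    sig <- outer(as.vector(base), rep(1, n)) *
      (1 + outer(as.vector(cvr_vec) / 100, dpet))
    if (spec$noise_sd > 0)
      sig <- sig + matrix(stats::rnorm(nv * n, sd = spec$noise_sd), nv, n)
    bold <- array(sig, c(spec$grid$shape, n))

    motion <- apply(matrix(stats::rnorm(n * 6L,
                                        sd = rep(c(spec$motion$step_sd_trans,
                                                   spec$motion$step_sd_rot),
                                                 each = 3L * n)),
                           n, 6L), 2, cumsum)
    colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")

    atlas_ref <- atlas_reference(
      mean = array(ifelse(m$brain, spec$atlas_mean, NA_real_),
                   spec$grid$shape),
      sd = array(ifelse(m$brain, spec$atlas_sd, NA_real_), spec$grid$shape),
      grid = spec$grid)

    structure(list(bold = bold, petco2 = pet, motion = motion,
                   protocol = protocol, grid = spec$grid,
                   brain_mask = m$brain, lesion_mask = m$lesion,
                   steal_truth = m$steal, cvr_truth = m$cvr,
                   territories = m$territories, atlas_ref = atlas_ref,
                   affected_side = spec$affected_side,
                   clinical = NULL, subject_id = subject_id),
              class = "subject_bundle")
  })
}

#' @export
print.subject_bundle <- function(x, ...) {
  cat(sprintf("subject bundle '%s': %s grid, %d frames%s\n", x$subject_id,
              paste(x$grid$shape, collapse = "x"), length(x$petco2),
              if (is.null(x$clinical)) "" else ", clinical record attached"))
  invisible(x)
}
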