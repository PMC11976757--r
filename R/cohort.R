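#' Specification of a synthetic stroke cohort
#'
#' Describes the joint statistical structure the cohort stage assumes:
#' positively skewed (log-normal) infarct lesion volumes, extra-lesional
#' steal volume rank-coupled to lesion volume through a Gaussian copula, a
#' beta-distributed fraction of the lesion covered by steal, clinical
#' covariates (age, admission NIHSS, groin-puncture-to-MR time), and a
#' discharge-NIHSS outcome drawn from a proportional-odds model. Defaults
#' emulate an early post-thrombectomy large-vessel-occlusion cohort: lesion
#' volumes with median ~26 mL and IQR ~15-53 mL, a target lesion/steal rank
#' correlation of 0.77, per-mL outcome effects of 0.04 (extra-lesional
#' steal) and 0.02 (lesion), -0.06 per year of age and 0.17 per admission
#' NIHSS point, and a quality-control failure rate of 5/26.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param lesion_lognorm `c(meanlog, sdlog)` of the lesion-volume law (mL).
#' @param steal_outside_association Target Spearman correlation between
#'   lesion volume and extra-lesional steal volume, in `[-1, 1]`.
#' @param steal_out_lognorm `c(meanlog, sdlog)` of the extra-lesional steal
#'   volume law (mL).
#' @param coverage_beta `c(shape1, shape2)` of the beta law for the fraction
#'   of the lesion covered by steal.
#' @param outcome_model List with `beta` (named effects of
#'   `steal_outside_ml`, `lesion_ml`, `age`, `nihss_admission` on the
#'   cumulative log-odds), `categories` (ordered outcome values) and
#'   `base_probs` (category probabilities at the reference linear
#'   predictor; cutpoints are derived from their cumulative logits).
#' @param age_normal `c(mean, sd)` of age (years), truncated to `[18, 100]`.
#' @param nihss_lognorm `c(meanlog, sdlog)` of admission NIHSS (rounded,
#'   clamped to 0-42).
#' @param groin_lognorm `c(meanlog, sdlog)` of groin-puncture-to-MR time (h).
#' @param qc_failure_rate Probability that a subject carries an injected
#'   quality failure (excessive motion or weak CO2 step, alternating).
#' @param qc_failures Optional exact number of failing subjects, overriding
#'   the Bernoulli draw.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 21L,
                        lesion_lognorm = c(meanlog = log(26.3),
                                           sdlog = 0.955),
                        steal_outside_association = 0.77,
                        steal_out_lognorm = c(meanlog = log(13.5),
                                              sdlog = 1.3),
                        coverage_beta = c(0.6, 1.8),
                        outcome_model = list(
                          beta = c(steal_outside_ml = 0.04,
                                   lesion_ml = 0.02,
                                   age = -0.06,
                                   nihss_admission = 0.17),
                          categories = 0:18,
                          base_probs = 0.75^(0:18) / sum(0.75^(0:18))),
                        age_normal = c(69, 15),
                        nihss_lognorm = c(meanlog = log(10), sdlog = 0.45),
                        groin_lognorm = c(meanlog = log(30), sdlog = 0.5),
                        qc_failure_rate = 5 / 26,
                        qc_failures = NULL,
                        seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1", call. = FALSE)
  if (abs(steal_outside_association) > 1)
    stop("target rank correlation must lie in [-1, 1]", call. = FALSE)
  if (qc_failure_rate < 0 || qc_failure_rate > 1)
    stop("qc_failure_rate must lie in [0, 1]", call. = FALSE)
  J <- length(outcome_model$categories)
  if (length(outcome_model$base_probs) != J ||
      any(outcome_model$base_probs <= 0))
    stop("outcome base_probs must be positive, one per category",
         call. = FALSE)
  cum <- cumsum(outcome_model$base_probs / sum(outcome_model$base_probs))[-J]
  if (is.unsorted(stats::qlogis(cum), strictly = TRUE))
    stop("derived cutpoints are not strictly increasing", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 lesion_lognorm = lesion_lognorm,
                 steal_outside_association = steal_outside_association,
                 steal_out_lognorm = steal_out_lognorm,
                 coverage_beta = coverage_beta,
                 outcome_model = outcome_model,
                 age_normal = age_normal, nihss_lognorm = nihss_lognorm,
                 groin_lognorm = groin_lognorm,
                 qc_failure_rate = qc_failure_rate,
                 qc_failures = qc_failures, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Pearson correlation of the Gaussian copula that yields Spearman rho_s.
copula_rho <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Cutpoints placing the base category probabilities at the reference linear
# predictor eta0 (medians/means of the covariate laws).
outcome_cutpoints <- function(spec) {
  om <- spec$outcome_model
  eta0 <- sum(om$beta * c(
    steal_outside_ml = exp(spec$steal_out_lognorm[["meanlog"]]),
    lesion_ml = exp(spec$lesion_lognorm[["meanlog"]]),
    age = spec$age_normal[1],
    nihss_admission = exp(spec$nihss_lognorm[["meanlog"]]))[names(om$beta)])
  J <- length(om$categories)
  stats::qlogis(cumsum(om$base_probs / sum(om$base_probs))[-J]) + eta0
}

#' Generate a synthetic cohort
#'
#' Draws the per-subject ground-truth table (volumes, covariates, injected
#' quality failures, discharge NIHSS from the proportional-odds outcome
#' model) and, optionally, full imaging bundles whose phantom geometry
#' realizes the drawn volumes on the voxel grid. The lesion/extra-lesional
#' steal dependence uses a Gaussian copula whose Pearson correlation
#' `2 sin(pi * rho_s / 6)` delivers the target Spearman correlation exactly
#' in population. Everything derives from `spec$seed`: the cohort table and
#' per-subject substream seeds are reproducible bit-for-bit.
#'
#' @param spec A [cohort_spec()].
#' @param images If `TRUE`, also synthesize a `subject_bundle` per subject
#'   (geometry quantized to the voxel grid, so realized mask volumes differ
#'   from the drawn ones by voxel-size rounding and clipping to the
#'   affected territory).
#' @param phantom Base [phantom_spec()] used for image synthesis.
#' @param protocol The [co2_protocol()] for image synthesis.
#' @return List with `table` (data frame, one row per subject), `cutpoints`
#'   used for the outcome draw, and `bundles` (list, only when
#'   `images = TRUE`).
#' @export
synthesize_cohort <- function(spec, images = FALSE,
                              phantom = phantom_spec(),
                              protocol = co2_protocol()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  with_seed(spec$seed, {
    if (n < 5 && spec$steal_outside_association != 0)
      warning("target rank correlation is only loosely controlled at n < 5")
    rho <- copula_rho(spec$steal_outside_association)
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
    lesion <- stats::qlnorm(stats::pnorm(z1),
                            spec$lesion_lognorm[["meanlog"]],
                            spec$lesion_lognorm[["sdlog"]])
    steal_out <- stats::qlnorm(stats::pnorm(z2),
                               spec$steal_out_lognorm[["meanlog"]],
                               spec$steal_out_lognorm[["sdlog"]])
    coverage <- stats::rbeta(n, spec$coverage_beta[1], spec$coverage_beta[2])
    steal_in <- coverage * lesion
    age <- pmin(pmax(stats::rnorm(n, spec$age_normal[1], spec$age_normal[2]),
                     18), 100)
    nihss0 <- pmin(pmax(round(stats::rlnorm(
      n, spec$nihss_lognorm[["meanlog"]], spec$nihss_lognorm[["sdlog"]])),
      0), 42)
    groin <- stats::rlnorm(n, spec$groin_lognorm[["meanlog"]],
                           spec$groin_lognorm[["sdlog"]])

    om <- spec$outcome_model
    alpha <- outcome_cutpoints(spec)
    covs <- cbind(steal_outside_ml = steal_out, lesion_ml = lesion,
                  age = age, nihss_admission = nihss0)
    eta <- drop(covs[, names(om$beta), drop = FALSE] %*% om$beta)
    latent <- eta + stats::rlogis(n)
    y <- om$categories[findInterval(latent, alpha) + 1L]

    fail <- if (!is.null(spec$qc_failures)) {
      f <- rep(FALSE, n)
      f[seq_len(min(spec$qc_failures, n))] <- TRUE
      f
    } else stats::runif(n) < spec$qc_failure_rate
    mode <- rep(NA_character_, n)
    mode[fail] <- rep(c("motion", "weak_stimulus"),
                      length.out = sum(fail))
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)

    tab <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      lesion_ml = lesion,
      steal_aca_mca_ml = steal_in + steal_out,
      steal_in_lesion_ml = steal_in,
      steal_outside_ml = steal_out,
      age = age, nihss_admission = nihss0, nihss_discharge = y,
      groin_to_mr_hours = groin,
      qc_fail_injected = fail, qc_fail_mode = mode,
      seed = sub_seeds, stringsAsFactors = FALSE)

    bundles <- NULL
    if (images) {
      bundles <- lapply(seq_len(n), function(i)
        cohort_subject_bundle(tab[i, ], phantom, protocol))
      for (i in seq_len(n)) {
        rs <- roi_row_from_truth(bundles[[i]])
        tab[i, names(rs)] <- rs
      }
    }
    list(table = tab, cutpoints = alpha, bundles = bundles)
  })
}

# Build one imaging bundle whose planted geometry approximates the drawn
# volumes: an ellipsoidal lesion (1:2:1 aspect, long axis
# anterior-posterior) centered in the affected MCA territory, a concentric
# steal core covering the drawn fraction of the lesion, and extra-lesional
# steal as a concentric shell around the lesion. Radii are clamped so all
# geometry stays inside the grid, so very large drawn volumes saturate;
# realized volumes are re-measured from the masks.
cohort_subject_bundle <- function(row, phantom, protocol) {
  grid <- phantom$grid
  shp <- grid$shape
  vml <- voxel_volume_ml(grid)
  aspect <- c(1, 2, 1)
  ctr <- c(0.75 * shp[1], 0.5 * shp[2], 0.5 * shp[3])
  # containment bound per axis for an ellipsoid at ctr with radii r * aspect
  rmax <- min((pmin(ctr, shp - ctr + 1) - 1) / aspect)
  r_unit <- function(vol_ml)
    (3 * (vol_ml / vml) / (4 * pi * prod(aspect)))^(1 / 3)
  r_les <- max(min(r_unit(row$lesion_ml), 0.8 * rmax), 0.6)
  r_in <- max(min(r_les * (row$steal_in_lesion_ml /
                             max(row$lesion_ml, 1e-9))^(1 / 3), r_les), 1e-3)
  scale_out <- (1 + row$steal_outside_ml / max(row$lesion_ml, 1e-3))^(1 / 3)
  r_out <- min(r_les * scale_out, rmax)
  regions <- list()
  if (r_in >= 0.5)
    regions <- c(regions, list(list(center = ctr, radii = r_in * aspect,
                                    where = "inside")))
  if (r_out > r_les)
    regions <- c(regions, list(list(center = ctr, radii = r_out * aspect,
                                    where = "outside")))
  if (length(regions) == 0)  # vanishing steal: keep a valid spec, no voxels
    regions <- list(list(center = ctr, radii = c(0.1, 0.1, 0.1),
                         where = "inside"))
  ph <- phantom_spec(grid_shape = shp, voxel_size = grid$voxel_size,
                     lesion_center = ctr, lesion_radii = r_les * aspect,
                     steal_regions = regions,
                     cvr_levels = phantom$cvr_levels,
                     baseline_signal = phantom$baseline_signal,
                     noise_sd = phantom$noise_sd,
                     hemodynamic_delay = phantom$hemodynamic_delay,
                     motion = phantom$motion,
                     atlas_mean = phantom$atlas_mean,
                     atlas_sd = phantom$atlas_sd,
                     affected_side = "right")
  proto <- protocol
  if (isTRUE(row$qc_fail_injected) && row$qc_fail_mode == "weak_stimulus")
    proto <- co2_protocol(protocol$resting_petco2, step_amplitude = 4,
                          protocol$baseline_s, protocol$step_s,
                          protocol$recovery_s, protocol$tr)
  b <- synthesize_subject(ph, proto, seed = row$seed,
                          subject_id = row$subject_id)
  if (isTRUE(row$qc_fail_injected) && row$qc_fail_mode == "motion") {
    fd <- framewise_displacement(b$motion)
    b$motion <- b$motion * (2.5 / max(mean(fd[-1]), 1e-9))
  }
  b$clinical <- row[c("subject_id", "age", "nihss_admission",
                      "nihss_discharge", "groin_to_mr_hours")]
  b
}

roi_row_from_truth <- function(bundle) {
  grid <- bundle$grid
  labs <- territory_labels()
  need <- labs$label[labs$hemisphere == bundle$affected_side &
                       labs$territory %in% c("ACA", "MCA")]
  aca_mca <- array(bundle$territories %in% need, grid$shape)
  sv <- bundle$steal_truth & aca_mca
  vml <- voxel_volume_ml(grid)
  c(lesion_ml = sum(bundle$lesion_mask) * vml,
    steal_aca_mca_ml = sum(sv) * vml,
    steal_in_lesion_ml = sum(sv & bundle$lesion_mask) * vml,
    steal_outside_ml = sum(sv & !bundle$lesion_mask) * vml)
}
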