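#' Healthy-reference CVR atlas
#'
#' Voxelwise mean and standard deviation of CVR in a healthy reference
#' cohort, on the same grid as the subject data. Used to standardize a
#' subject's CVR map into Z-scores.
#'
#' @param mean,sd 3D arrays of CVR mean and SD (%/mmHg); `NA` outside the
#'   reference brain mask. `sd` must be strictly positive wherever defined.
#' @param grid The shared [volume_grid()].
#' @return Object of class `atlas_reference`.
#' @export
atlas_reference <- function(mean, sd, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  if (!identical(dim(mean), grid$shape) || !identical(dim(sd), grid$shape))
    stop("grid mismatch: atlas maps do not match the declared grid",
         call. = FALSE)
  if (any(sd[!is.na(sd)] <= 0))
    stop("atlas SD must be strictly positive inside the reference mask",
         call. = FALSE)
  structure(list(mean = mean, sd = sd, grid = grid),
            class = "atlas_reference")
}

#' Baseline-centered stimulus regressor
#'
#' Shifts the PetCO2 trace by the hemodynamic delay (nearest frame, padding
#' the start with the first sample) and centers it on its baseline-epoch
#' mean, producing the regressor the voxelwise fit uses.
#'
#' @param petco2 Per-frame PetCO2 trace (mmHg).
#' @param protocol The [co2_protocol()] describing the epochs.
#' @param delay Hemodynamic delay in seconds; must satisfy
#'   `0 <= delay < baseline_s`.
#' @return Numeric vector, one value per frame.
#' @export
build_regressor <- function(petco2, protocol, delay = 0) {
  stopifnot(inherits(protocol, "co2_protocol"))
  n <- length(petco2)
  if (delay < 0 || delay >= protocol$baseline_s)
    stop("delay must be >= 0 s and smaller than the baseline duration",
         call. = FALSE)
  k <- as.integer(round(delay / protocol$tr))
  shifted <- if (k > 0) c(rep(petco2[1], k), petco2[seq_len(n - k)])
             else petco2
  ep <- protocol_epochs(protocol, n)
  if (length(ep$baseline) == 0)
    stop("trace does not cover the baseline epoch", call. = FALSE)
  shifted - mean(shifted[ep$baseline])
}

#' Voxelwise cerebrovascular reactivity map
#'
#' Computes CVR voxel-per-voxel as the percentage BOLD signal change per
#' mmHg change of end-tidal CO2. Each voxel's signal is regressed (ordinary
#' least squares, intercept included) on the delayed, baseline-centered
#' PetCO2 regressor; the slope is converted to percent of the voxel's
#' baseline-epoch mean signal:
#' `CVR = 100 * slope / baseline_mean` (%/mmHg).
#' On an ideal noiseless step this reduces exactly to
#' `(plateau mean - baseline mean) / (step * baseline mean) * 100`.
#'
#' Voxels with non-positive baseline signal, or outside `brain_mask` when
#' one is given, are flagged undefined (`NA`), never zero-filled.
#'
#' @param bold 4D array (x, y, z, frames).
#' @param petco2 Per-frame PetCO2 trace; must match the frame count.
#' @param protocol The [co2_protocol()].
#' @param grid The [volume_grid()] of the acquisition.
#' @param brain_mask Optional logical 3D array restricting the fit.
#' @param delay Hemodynamic delay in seconds (see [build_regressor()]).
#' @return Object of class `cvr_map` with elements `values` (3D array,
#'   `NA` where undefined), `grid`, `brain_mask` (voxels where CVR is
#'   defined) and `params`.
#' @export
compute_cvr <- function(bold, petco2, protocol, grid,
                        brain_mask = NULL, delay = 0) {
  dm <- dim(bold)
  if (length(dm) != 4L)
    stop("bold must be a 4D array", call. = FALSE)
  if (dm[4] != length(petco2))
    stop("alignment error: BOLD has ", dm[4], " frames but the PetCO2 trace ",
         length(petco2), call. = FALSE)
  if (!identical(dm[1:3], grid$shape))
    stop("grid mismatch: BOLD volume does not match the declared grid",
         call. = FALSE)
  x <- build_regressor(petco2, protocol, delay)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  if (sxx == 0)
    stop("stimulus error: PetCO2 regressor has zero variance", call. = FALSE)
  nv <- prod(dm[1:3])
  sig <- matrix(bold, nv, dm[4])
  ep <- protocol_epochs(protocol, dm[4])
  m0 <- rowMeans(sig[, ep$baseline, drop = FALSE])
  slope <- as.vector(sig %*% xc) / sxx
  defined <- m0 > 0
  if (!is.null(brain_mask)) {
    stopifnot(identical(dim(brain_mask), grid$shape))
    defined <- defined & as.vector(brain_mask)
  }
  vals <- rep(NA_real_, nv)
  vals[defined] <- 100 * slope[defined] / m0[defined]
  if (!any(defined))
    stop("brain mask is empty: no voxel has positive baseline signal",
         call. = FALSE)
  structure(list(values = array(vals, dm[1:3]), grid = grid,
                 brain_mask = array(defined, dm[1:3]),
                 params = list(delay = delay)),
            class = "cvr_map")
}

#' @export
print.cvr_map <- function(x, ...) {
  v <- x$values[x$brain_mask]
  cat(sprintf("CVR map: %s grid, %d defined voxels, mean %.3f %%/mmHg (range %.3f to %.3f)\n",
              paste(x$grid$shape, collapse = "x"), length(v), mean(v),
              min(v), max(v)))
  invisible(x)
}

#' Atlas-referenced Z-score map of a CVR map
#'
#' Standardizes the subject's CVR against the healthy reference:
#' `Z = (CVR - atlas mean) / atlas SD`, voxelwise. Undefined wherever the
#' CVR map or the atlas is undefined.
#'
#' @param cvr A [compute_cvr()] result.
#' @param atlas An [atlas_reference()] on the same grid.
#' @return Object of class `z_map` with `values`, `grid`.
#' @export
zscore_map <- function(cvr, atlas) {
  stopifnot(inherits(cvr, "cvr_map"), inherits(atlas, "atlas_reference"))
  check_same_grid(cvr$grid, atlas$grid, "CVR map and atlas")
  z <- (cvr$values - atlas$mean) / atlas$sd
  structure(list(values = z, grid = cvr$grid), class = "z_map")
}
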