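#' Framewise displacement from a 6-dof motion trace
#'
#' Power-style framewise displacement: the sum of absolute backward
#' differences of the three translations (mm) plus the three rotations
#' converted to arc length on a sphere of radius `rotation_radius` mm.
#' `FD(t) = sum_i |d tx_i| + radius * sum_j |d r_j|`, with `FD(1) = 0`.
#'
#' @param motion Numeric matrix with one row per frame and six columns:
#'   three translations in mm, then three rotations in radians.
#' @param rotation_radius Sphere radius (mm) for the rotation term.
#' @return Numeric vector of per-frame FD (mm), same length as the frame
#'   count; the first element is 0.
#' @export
framewise_displacement <- function(motion, rotation_radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L)
    stop("motion trace must have six columns (3 translations, 3 rotations)",
         call. = FALSE)
  if (nrow(motion) < 2L)
    stop("motion trace needs at least two frames", call. = FALSE)
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      rotation_radius * rowSums(d[, 4:6, drop = FALSE]))
}

#' Realized CO2 step magnitude
#'
#' The difference between the median PetCO2 of the step plateau and the
#' median of the baseline epoch. Medians (rather than means) make the
#' statistic robust to transient sampling spikes, and the first `trim_s`
#' seconds after each stimulus transition are dropped so ramp frames do not
#' dilute the plateau.
#'
#' @param petco2 Per-frame PetCO2 trace (mmHg).
#' @param protocol The [co2_protocol()] declaring the epochs.
#' @param trim_s Seconds trimmed after each transition (default 10).
#' @return Step magnitude in mmHg.
#' @export
co2_step_magnitude <- function(petco2, protocol, trim_s = 10) {
  ep <- protocol_epochs(protocol, length(petco2), trim_s = trim_s)
  if (length(ep$baseline) == 0 || length(ep$plateau) == 0)
    stop("trace does not cover both the baseline and plateau epochs",
         call. = FALSE)
  stats::median(petco2[ep$plateau]) - stats::median(petco2[ep$baseline])
}

#' Quality-control gate for one subject
#'
#' Applies the two exclusion rules: a subject fails on motion when the mean
#' framewise displacement between adjacent volumes exceeds `fd_threshold`
#' (strictly), and on stimulus adequacy when the realized CO2 step is
#' strictly below `step_threshold`. The mean FD averages over the
#' `n - 1` adjacent-volume displacements.
#'
#' @param bundle A `subject_bundle` (needs `motion`, `petco2`, `protocol`).
#' @param fd_threshold Mean-FD exclusion threshold in mm (default 2).
#' @param step_threshold Minimum acceptable CO2 step in mmHg (default 6).
#' @param rotation_radius Passed to [framewise_displacement()].
#' @return Object of class `qc_report`: `mean_fd`, `max_fd`, `co2_step`,
#'   `passed`, `reasons` (empty iff passed).
#' @export
qc_subject <- function(bundle, fd_threshold = 2, step_threshold = 6,
                       rotation_radius = 50) {
  fd <- framewise_displacement(bundle$motion, rotation_radius)
  mean_fd <- mean(fd[-1])
  step <- co2_step_magnitude(bundle$petco2, bundle$protocol)
  reasons <- character(0)
  if (mean_fd > fd_threshold) reasons <- c(reasons, "motion")
  if (step < step_threshold) reasons <- c(reasons, "weak_stimulus")
  structure(list(subject_id = bundle$subject_id, mean_fd = mean_fd,
                 max_fd = max(fd), co2_step = step,
                 passed = length(reasons) == 0L, reasons = reasons,
                 thresholds = list(mean_fd = fd_threshold,
                                   co2_step = step_threshold)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC %s [%s]: mean FD %.3f mm (max %.3f), CO2 step %.2f mmHg%s\n",
              x$subject_id, if (x$passed) "pass" else "FAIL",
              x$mean_fd, x$max_fd, x$co2_step,
              if (x$passed) "" else paste0(" - ",
                                           paste(x$reasons, collapse = ", "))))
  invisible(x)
}

qc_report_json <- function(report) {
  jsonlite::toJSON(report[c("subject_id", "mean_fd", "max_fd", "co2_step",
                            "passed", "reasons")],
                   auto_unbox = TRUE, digits = NA)
}
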