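#' Hypercapnic step-challenge protocol
#'
#' Describes the boxcar end-tidal CO2 (PetCO2) stimulus used for CVR mapping:
#' a baseline epoch at the subject's resting PetCO2, a hypercapnic step, and a
#' return to baseline. The default is the standard clinical protocol of 100 s
#' baseline, an 80 s step of +10 mmHg, and 120 s recovery, sampled once per
#' 2 s volume repetition time.
#'
#' @param resting_petco2 Resting end-tidal CO2 in mmHg.
#' @param step_amplitude Height of the hypercapnic step in mmHg. May be any
#'   real value; quality control downstream decides whether the realized step
#'   is adequate.
#' @param baseline_s,step_s,recovery_s Epoch durations in seconds; all must
#'   be strictly positive.
#' @param tr Sampling interval (volume repetition time) in seconds.
#' @return An object of class `co2_protocol`.
#' @examples
#' p <- co2_protocol()
#' length(petco2_trace(p))  # 150 frames
#' @export
co2_protocol <- function(resting_petco2 = 38, step_amplitude = 10,
                         baseline_s = 100, step_s = 80, recovery_s = 120,
                         tr = 2) {
  for (nm in c("baseline_s", "step_s", "recovery_s", "tr")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("invalid protocol: '", nm, "' must be a positive number", call. = FALSE)
  }
  stopifnot(is.numeric(resting_petco2), is.numeric(step_amplitude))
  structure(list(resting_petco2 = resting_petco2,
                 step_amplitude = step_amplitude,
                 baseline_s = baseline_s, step_s = step_s,
                 recovery_s = recovery_s, tr = tr),
            class = "co2_protocol")
}

#' @export
print.co2_protocol <- function(x, ...) {
  cat(sprintf(
    "CO2 step protocol: %g s baseline @ %g mmHg, %g s step of %+g mmHg, %g s recovery (TR %g s, %d frames)\n",
    x$baseline_s, x$resting_petco2, x$step_s, x$step_amplitude,
    x$recovery_s, x$tr, n_frames(x)))
  invisible(x)
}

total_duration <- function(protocol)
  protocol$baseline_s + protocol$step_s + protocol$recovery_s

n_frames <- function(protocol)
  as.integer(ceiling(total_duration(protocol) / protocol$tr))

frame_times <- function(protocol, n = n_frames(protocol))
  (seq_len(n) - 1) * protocol$tr

#' Ideal PetCO2 trace for a protocol
#'
#' Samples the boxcar stimulus at the volume acquisition times: frame i
#' (0-based) is acquired at `i * tr` and takes the resting value during
#' baseline and recovery and `resting + step_amplitude` during the step
#' epoch. Epochs are half-open intervals, so a frame on an epoch boundary
#' belongs to the later epoch.
#'
#' @param protocol A [co2_protocol()].
#' @return Numeric vector of PetCO2 (mmHg), one value per frame
#'   (`ceiling(total_duration / tr)` frames).
#' @export
petco2_trace <- function(protocol) {
  stopifnot(inherits(protocol, "co2_protocol"))
  t <- frame_times(protocol)
  on_step <- t >= protocol$baseline_s &
    t < protocol$baseline_s + protocol$step_s
  protocol$resting_petco2 + protocol$step_amplitude * on_step
}

#' Frame indices for each protocol epoch
#'
#' Maps the protocol's epoch boundaries onto a trace of `n` frames. When
#' `trim_s > 0`, frames within `trim_s` seconds after a transition (start of
#' the step and start of recovery) are dropped from those epochs, which
#' excludes transition/ramp frames from epoch summary statistics. The
#' baseline epoch starts at scan onset and is never trimmed.
#'
#' @param protocol A [co2_protocol()].
#' @param n Number of frames in the trace being indexed.
#' @param trim_s Seconds to drop after each stimulus transition.
#' @return List with integer index vectors `baseline`, `plateau`, `recovery`.
#' @export
protocol_epochs <- function(protocol, n = n_frames(protocol), trim_s = 0) {
  stopifnot(inherits(protocol, "co2_protocol"), n >= 1, trim_s >= 0)
  t <- frame_times(protocol, n)
  t_step <- protocol$baseline_s
  t_rec <- protocol$baseline_s + protocol$step_s
  list(baseline = which(t < t_step),
       plateau  = which(t >= t_step + trim_s & t < t_rec),
       recovery = which(t >= t_rec + trim_s))
}
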