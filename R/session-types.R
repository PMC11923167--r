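#' Photometry session
#'
#' Container for one demodulated fiber-photometry recording: a signal channel
#' (465 nm GCaMP or 560 nm red dopamine sensor excitation) and the 405 nm UV
#' isosbestic reference on a shared uniform time grid, plus TTL event marks.
#'
#' @param t Time (s), strictly increasing uniform grid.
#' @param signal Demodulated signal-channel fluorescence (a.u.).
#' @param reference Demodulated isosbestic reference fluorescence (a.u.).
#' @param sample_rate Sampling rate in Hz (nominal 1000).
#' @param signal_wavelength Excitation wavelength of the signal channel,
#'   465 or 560.
#' @param events Data frame with columns \code{timestamp} (s) and
#'   \code{label}; may have zero rows.
#' @return An object of class \code{photometry_session}.
#' @export
photometry_session <- function(t, signal, reference, sample_rate = 1000,
                               signal_wavelength = 465,
                               events = empty_events()) {
  x <- structure(
    list(t = as.numeric(t), signal = as.numeric(signal),
         reference = as.numeric(reference),
         sample_rate = as.numeric(sample_rate),
         signal_wavelength = signal_wavelength,
         events = tibble::as_tibble(events)),
    class = "photometry_session"
  )
  validate_photometry_session(x)
}

empty_events <- function() tibble::tibble(timestamp = numeric(0), label = character(0))

check_uniform_grid <- function(t, sample_rate, what = "t", tol = 1e-9) {
  if (length(t) < 2) return(invisible(TRUE))
  dt <- diff(t)
  if (any(dt <= 0)) sf_timing_error(paste0(what, " must be strictly increasing"))
  if (max(abs(dt - 1 / sample_rate)) > tol)
    sf_timing_error(sprintf(
      "%s is not a uniform grid at %g Hz (max step deviation %.3g s)",
      what, sample_rate, max(abs(dt - 1 / sample_rate))))
  invisible(TRUE)
}

validate_photometry_session <- function(x) {
  n <- length(x$t)
  if (length(x$signal) != n || length(x$reference) != n)
    sf_schema_error("signal and reference must have the same length as t")
  check_uniform_grid(x$t, x$sample_rate, "photometry t")
  if (!all(c("timestamp", "label") %in% names(x$events)))
    sf_schema_error("events must have columns 'timestamp' and 'label'")
  if (nrow(x$events) > 0) {
    if (any(x$events$timestamp < x$t[1] - 1e-9) ||
        any(x$events$timestamp > x$t[n] + 1e-9))
      sf_timing_error("event timestamps must lie within the recorded span")
  }
  if (!x$signal_wavelength %in% c(465, 560))
    sf_schema_error("signal_wavelength must be 465 or 560")
  x
}

#' Behavior track
#'
#' Velocity trace from the treadmill rotary encoder (calibrated 10 cm/s at
#' 2.5 V, i.e. 4 cm s^-1 V^-1) or from open-field video tracking, optionally
#' with a normalized motion index in [0, 1] (video pixel-change proxy).
#'
#' @param t Time (s), uniform grid.
#' @param velocity Velocity (cm/s), finite.
#' @param motion_index Optional motion index in [0, 1], same length as t.
#' @param sample_rate Sampling rate (Hz).
#' @param calibration Encoder calibration, cm/s per volt (default 4).
#' @return An object of class \code{behavior_track}.
#' @export
behavior_track <- function(t, velocity, motion_index = NULL,
                           sample_rate = 1000, calibration = 4) {
  x <- structure(
    list(t = as.numeric(t), velocity = as.numeric(velocity),
         motion_index = if (is.null(motion_index)) NULL else as.numeric(motion_index),
         sample_rate = as.numeric(sample_rate), calibration = calibration),
    class = "behavior_track"
  )
  validate_behavior_track(x)
}

validate_behavior_track <- function(x) {
  if (length(x$velocity) != length(x$t))
    sf_schema_error("velocity must have the same length as t")
  check_uniform_grid(x$t, x$sample_rate, "behavior t")
  if (any(!is.finite(x$velocity)))
    sf_numeric_error("velocity contains non-finite values")
  if (!is.null(x$motion_index)) {
    if (length(x$motion_index) != length(x$t))
      sf_schema_error("motion_index must have the same length as t")
    if (any(x$motion_index < 0 | x$motion_index > 1, na.rm = TRUE))
      sf_numeric_error("motion_index must lie in [0, 1]")
  }
  x
}

#' Stimulation protocol
#'
#' Optogenetic stimulation schedule: onset times and durations of light
#' trials, with pulse parameters. `schedule_kind` distinguishes the 3-min
#' ON/OFF epoch design, the 10-s trial design, and mixed-duration trials
#' (2/5/15 s).
#'
#' @param trial_onsets Trial onset times (s), sorted.
#' @param trial_durations Trial durations (s), length 1 (recycled) or one per
#'   trial.
#' @param pulse_frequency Pulse rate in Hz (0 = constant light).
#' @param pulse_width Pulse width in ms.
#' @param power Light power in mW.
#' @param schedule_kind One of "epoch_3min", "trial_10s", "trial_varied".
#' @return An object of class \code{stim_protocol}.
#' @export
stim_protocol <- function(trial_onsets, trial_durations,
                          pulse_frequency = 20, pulse_width = 5, power = 3,
                          schedule_kind = c("trial_varied", "trial_10s",
                                            "epoch_3min")) {
  schedule_kind <- match.arg(schedule_kind)
  onsets <- as.numeric(trial_onsets)
  durs <- rep_len(as.numeric(trial_durations), length(onsets))
  x <- structure(
    list(trial_onsets = onsets, trial_durations = durs,
         pulse_frequency = pulse_frequency, pulse_width = pulse_width,
         power = power, schedule_kind = schedule_kind),
    class = "stim_protocol"
  )
  validate_stim_protocol(x)
}

validate_stim_protocol <- function(x) {
  if (is.unsorted(x$trial_onsets, strictly = TRUE) && length(x$trial_onsets) > 1)
    sf_schema_error("trial onsets must be sorted and distinct")
  if (any(x$trial_durations <= 0))
    sf_schema_error("trial durations must be positive")
  if (length(x$trial_onsets) > 1) {
    offs <- x$trial_onsets + x$trial_durations
    if (any(offs[-length(offs)] > x$trial_onsets[-1] + 1e-9))
      sf_schema_error("stimulation trials must not overlap")
  }
  x
}

#' Session bundle
#'
#' One recording session: any combination of photometry, behavior and
#' stimulation protocol sharing a common clock (seconds). At least one
#' component must be present.
#'
#' @param photometry A [photometry_session()] or NULL.
#' @param behavior A [behavior_track()] or NULL.
#' @param stim A [stim_protocol()] or NULL.
#' @param subject_id Subject identifier string.
#' @param meta Free-form named list of metadata.
#' @return An object of class \code{session_bundle}.
#' @export
session_bundle <- function(photometry = NULL, behavior = NULL, stim = NULL,
                           subject_id = "unknown", meta = list()) {
  if (is.null(photometry) && is.null(behavior) && is.null(stim))
    sf_schema_error("a session bundle needs at least one component")
  structure(
    list(photometry = photometry, behavior = behavior, stim = stim,
         subject_id = subject_id, meta = meta),
    class = "session_bundle"
  )
}

#' @export
print.photometry_session <- function(x, ...) {
  cat(sprintf("<photometry_session> %d samples @ %g Hz, signal %g nm, %d events\n",
              length(x$t), x$sample_rate, x$signal_wavelength, nrow(x$events)))
  invisible(x)
}

#' @export
print.behavior_track <- function(x, ...) {
  cat(sprintf("<behavior_track> %d samples @ %g Hz%s\n", length(x$t),
              x$sample_rate,
              if (is.null(x$motion_index)) "" else ", with motion_index"))
  invisible(x)
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol> %s: %d trials, %g Hz pulses @ %g mW\n",
              x$schedule_kind, length(x$trial_onsets), x$pulse_frequency,
              x$power))
  invisible(x)
}

#' @export
print.session_bundle <- function(x, ...) {
  cat(sprintf("<session_bundle> subject %s [%s]\n", x$subject_id,
              paste(c("photometry", "behavior", "stim")[
                !vapply(list(x$photometry, x$behavior, x$stim), is.null,
                        logical(1))], collapse = " + ")))
  invisible(x)
}
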