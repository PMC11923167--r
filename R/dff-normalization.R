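#' Sliding-percentile baseline F0
#'
#' Estimates the slow baseline F0 of a raw fluorescence trace as the running
#' p-th percentile over a sliding window (default: 10th percentile, 5-s
#' window), tracking photobleaching and other slow correlated changes shared
#' by both channels. The window is centered on each sample and truncated at
#' the trace edges; percentiles use linear interpolation between order
#' statistics (R quantile type 7).
#'
#' @param trace Raw fluorescence (a.u.).
#' @param rate Sampling rate (Hz).
#' @param window Window length (s), default 5.
#' @param percentile Percentile in (0, 100), default 10.
#' @return Baseline trace, same length as \code{trace}.
#' @export
sliding_percentile_baseline <- function(trace, rate, window = 5,
                                        percentile = 10) {
  if (!is.finite(window) || window <= 0)
    sf_param_error("window must be a positive duration in seconds")
  if (percentile <= 0 || percentile >= 100)
    sf_param_error("percentile must lie strictly between 0 and 100")
  n <- length(trace)
  w <- round(window * rate)
  if (n <= w)
    sf_param_error(sprintf(
      "trace (%d samples) must be longer than the %g-s window (%d samples)",
      n, window, w))
  half <- floor(w / 2)
  .sliding_percentile_cpp(as.numeric(trace), as.integer(half),
                          percentile / 100)
}

#' Pre-normalize a channel to dF/F0
#'
#' Elementwise \code{(trace - f0) / f0}. Both the signal and the isosbestic
#' reference channel are pre-normalized this way in the locomotion
#' (behavior-mode) pipeline before referencing.
#'
#' @param trace Raw fluorescence (a.u.).
#' @param f0 Baseline from [sliding_percentile_baseline()]; must be strictly
#'   positive.
#' @return dF/F0 series (dimensionless fraction).
#' @export
prenormalize_dff <- function(trace, f0) {
  if (length(trace) != length(f0))
    sf_schema_error("trace and f0 must have equal length")
  bad <- which(f0 <= 0)
  if (length(bad) > 0)
    sf_numeric_error(sprintf(
      "baseline f0 is non-positive at sample %d (value %g); dF/F undefined",
      bad[1], f0[bad[1]]))
  (trace - f0) / f0
}

#' Zero-phase low-pass Butterworth filter
#'
#' Forward-backward (zero-phase) application of a low-pass Butterworth
#' filter, used on the reference-channel dF/F0 before the referencing
#' regression so the reference is not phase-shifted relative to the signal.
#' Because of the two passes the effective attenuation order is twice
#' \code{order}.
#'
#' @param x Input series.
#' @param rate Sampling rate (Hz).
#' @param corner Corner frequency (Hz), default 3.
#' @param order Filter order per pass, default 2.
#' @return Filtered series.
#' @export
lowpass_zero_phase <- function(x, rate, corner = 3, order = 2) {
  if (corner <= 0 || corner >= rate / 2)
    sf_param_error("corner frequency must lie in (0, rate/2)")
  bf <- signal::butter(order, corner / (rate / 2), type = "low")
  as.numeric(signal::filtfilt(bf, as.numeric(x)))
}

#' Behavior-mode reference correction
#'
#' The locomotion-recording referencing dialect: the pre-normalized
#' reference dF/F0 is low-pass filtered (zero-phase Butterworth, 3 Hz corner,
#' 2nd order), a RANSAC linear regression of the signal dF/F0 on the filtered
#' reference estimates gain and offset between the channels, and the
#' transformed reference is subtracted from the signal dF/F0 to give the
#' final dF/F. The transformed reference is returned alongside (it serves as
#' the UV dF/F in quality control).
#'
#' @param signal_dff Signal-channel dF/F0 from [prenormalize_dff()].
#' @param ref_dff Reference-channel dF/F0.
#' @param rate Sampling rate (Hz).
#' @param params [analysis_params()].
#' @param seed Optional seed for the RANSAC draw.
#' @return List with \code{dff} (corrected series), \code{ref_transformed},
#'   and \code{fit} (the [ransac_lm()] result).
#' @export
reference_correct_behavior <- function(signal_dff, ref_dff, rate,
                                       params = analysis_params(),
                                       seed = NULL) {
  if (length(signal_dff) != length(ref_dff))
    sf_schema_error("signal and reference series must have equal length")
  ref_filt <- lowpass_zero_phase(ref_dff, rate, corner = params$butter_corner,
                                 order = params$butter_order)
  fit <- ransac_lm(ref_filt, signal_dff, n_iter = params$ransac_iter,
                   min_inlier_frac = params$ransac_min_inlier_frac,
                   seed = seed)
  ref_tr <- fit$slope * ref_filt + fit$intercept
  list(dff = signal_dff - ref_tr, ref_transformed = ref_tr, fit = fit)
}

#' Stimulation-mode normalization
#'
#' The stimulation-recording dialect, designed to survive the large offset
#' the light pulses add: a RANSAC linear regression between the raw
#' demodulated reference and raw demodulated signal transforms the reference
#' into a predicted baseline F (absorbing gain and offset differences, motion
#' artifacts and photobleaching); then dF = signal - F and dF/F = dF / F.
#' No percentile baseline and no pre-filtering are involved; F comes entirely
#' from the regression.
#'
#' @param signal_raw Raw demodulated signal channel (a.u.).
#' @param ref_raw Raw demodulated isosbestic reference (a.u.).
#' @param rate Sampling rate (Hz).
#' @param params [analysis_params()].
#' @param seed Optional seed for the RANSAC draw.
#' @return A \code{normalized_trace} list: \code{t} is NULL until attached by
#'   the caller; \code{dff}, \code{f0} (the referenced F), \code{zscore},
#'   \code{method = "stim_mode"}.
#' @export
reference_correct_stim <- function(signal_raw, ref_raw, rate,
                                   params = analysis_params(), seed = NULL) {
  if (length(signal_raw) != length(ref_raw))
    sf_schema_error("signal and reference series must have equal length")
  fit <- ransac_lm(ref_raw, signal_raw, n_iter = params$ransac_iter,
                   min_inlier_frac = params$ransac_min_inlier_frac,
                   seed = seed)
  f <- fit$slope * ref_raw + fit$intercept
  bad <- which(f <= 0)
  if (length(bad) > 0)
    sf_numeric_error(sprintf(
      "referenced F is non-positive at sample %d; cannot form dF/F", bad[1]))
  dff <- (signal_raw - f) / f
  z <- if (stats::sd(dff) > 0) zscore_session(dff) else rep(0, length(dff))
  structure(list(t = NULL, dff = dff, zscore = z, f0 = f,
                 method = "stim_mode", fit = fit,
                 params_used = params[c("ransac_iter",
                                        "ransac_min_inlier_frac")]),
            class = "normalized_trace")
}

#' Full behavior-mode normalization of a photometry session
#'
#' Convenience wrapper running the whole locomotion dialect on a
#' [photometry_session()]: sliding-percentile F0 on both channels,
#' pre-normalization to dF/F0, zero-phase filtering + RANSAC referencing,
#' session z-scoring and quality control.
#'
#' @param session A [photometry_session()].
#' @param params [analysis_params()].
#' @param seed Optional seed for the RANSAC draw.
#' @return A \code{normalized_trace} with fields \code{t}, \code{dff},
#'   \code{zscore}, \code{f0} (signal-channel baseline),
#'   \code{ref_transformed}, \code{qc} (a [qc_session()] result) and
#'   \code{method = "behavior_mode"}.
#' @export
normalize_behavior_session <- function(session, params = analysis_params(),
                                       seed = NULL) {
  stopifnot(inherits(session, "photometry_session"))
  rate <- session$sample_rate
  f0_sig <- sliding_percentile_baseline(session$signal, rate,
                                        window = params$f0_window,
                                        percentile = params$f0_percentile)
  f0_ref <- sliding_percentile_baseline(session$reference, rate,
                                        window = params$f0_window,
                                        percentile = params$f0_percentile)
  sig_dff <- prenormalize_dff(session$signal, f0_sig)
  ref_dff <- prenormalize_dff(session$reference, f0_ref)
  corr <- reference_correct_behavior(sig_dff, ref_dff, rate, params, seed)
  qc <- qc_session(corr$dff, corr$ref_transformed, params)
  structure(list(t = session$t, dff = corr$dff,
                 zscore = zscore_session(corr$dff), f0 = f0_sig,
                 ref_transformed = corr$ref_transformed, qc = qc,
                 method = "behavior_mode",
                 params_used = params[c("f0_window", "f0_percentile",
                                        "butter_order", "butter_corner",
                                        "qc_max_dff", "qc_max_corr")]),
            class = "normalized_trace")
}

#' Session quality control
#'
#' A session is included only when the signal is strong enough and not
#' motion-dominated: maximum dF/F (in percent) must exceed
#' \code{qc_max_dff} (default 1.5) AND the Pearson correlation between the
#' final dF/F and the transformed UV reference must stay below
#' \code{qc_max_corr} (default 0.6). A zero-variance input makes the
#' correlation undefined and excludes the session with a reason flag.
#'
#' @param dff Final dF/F series (dimensionless fraction).
#' @param ref_series Transformed reference series.
#' @param params [analysis_params()].
#' @return List of class \code{qc_result}: \code{max_dff} (percent),
#'   \code{signal_ref_corr}, \code{included}, \code{reason}.
#' @export
qc_session <- function(dff, ref_series, params = analysis_params()) {
  if (length(dff) != length(ref_series))
    sf_schema_error("dff and reference series must have equal length")
  max_dff_pct <- max(dff) * 100
  if (stats::sd(dff) == 0 || stats::sd(ref_series) == 0) {
    return(structure(list(max_dff = max_dff_pct, signal_ref_corr = NA_real_,
                          included = FALSE,
                          reason = "zero-variance input; correlation undefined"),
                     class = "qc_result"))
  }
  r <- stats::cor(dff, ref_series)
  included <- (max_dff_pct > params$qc_max_dff) && (r < params$qc_max_corr)
  reason <- if (included) "passed" else if (max_dff_pct <= params$qc_max_dff)
    "low signal (max dF/F below threshold)" else
    "motion-contaminated (signal/reference correlation too high)"
  structure(list(max_dff = max_dff_pct, signal_ref_corr = r,
                 included = included, reason = reason),
            class = "qc_result")
}

#' Session z-score
#'
#' Standardizes a dF/F series with the mean and standard deviation of the
#' entire recording session.
#'
#' @param dff dF/F series.
#' @return z-scored series (mean 0, SD 1 over the session).
#' @export
zscore_session <- function(dff) {
  s <- stats::sd(dff)
  if (!is.finite(s) || s == 0)
    sf_numeric_error("session SD is zero; z-score undefined")
  (dff - mean(dff)) / s
}

#' @export
print.normalized_trace <- function(x, ...) {
  cat(sprintf("<normalized_trace> %s, %d samples, max dF/F %.3g%%\n",
              x$method, length(x$dff), max(x$dff) * 100))
  if (!is.null(x$qc))
    cat(sprintf("  QC: %s (max dF/F %.2f%%, r = %.3f)\n",
                if (x$qc$included) "included" else "excluded",
                x$qc$max_dff, x$qc$signal_ref_corr))
  invisible(x)
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("<qc_result> %s: max dF/F %.3f%%, signal/ref r = %s\n",
              if (x$included) "included" else "excluded", x$max_dff,
              format(x$signal_ref_corr, digits = 3)))
  if (!x$included) cat("  reason:", x$reason, "\n")
  invisible(x)
}
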