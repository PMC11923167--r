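# Synthetic-session generator. Emulates the statistical structure the
# analyses assume -- exponential photobleaching, a low-pass-filtered motion
# artifact shared across channels, event-locked double-exponential calcium
# transients with a configurable lead/lag relative to locomotion onset,
# bout-structured velocity, and boxcar/ramp/rebound stimulation responses --
# with exact ground truth for parameter-recovery tests. It makes no claim of
# biophysical realism (no spiking, sensor saturation or hemodynamics).
#
# RNG discipline: every generator draws a fixed number of variates in a fixed
# order, so two runs with the same seed differing only in a gain (e.g.
# motion_amp = 0) produce identical noise and transients. When `seed` is set,
# simulate_locomotion uses it directly and simulate_photometry /
# simulate_stim_session use seed + 1 and seed + 2, keeping the streams
# independent yet reproducible.

#' Synthetic-session configuration
#'
#' Parameters of the synthetic generator. Defaults describe a 30-min
#' head-fixed treadmill session sampled at 1 kHz with slow photobleaching,
#' GCaMP8s-like transient kinetics, a band-limited shared motion artifact, and a
#' mouse that initiates about two slow walking bouts per minute.
#'
#' @param duration Session length (s).
#' @param rate Sampling rate (Hz).
#' @param baseline_F Initial fluorescence level (a.u.).
#' @param bleach_amp Total fluorescence lost to photobleaching (a.u.); the
#'   bleaching curve is \code{baseline_F - bleach_amp * (1 - exp(-t / bleach_tau))}.
#' @param bleach_tau Photobleaching e-fold time (s).
#' @param rise_tau,decay_tau,transient_amp Double-exponential transient
#'   kernel: rise and decay time constants (s) and peak amplitude (a.u.).
#' @param event_lag Signed lag (s) of neural transients relative to
#'   locomotion onset; negative means activity leads movement.
#' @param offset_slope_sign +1 or -1: direction of the activity trend into
#'   locomotion offset.
#' @param offset_ramp_amp Amplitude (a.u.) reached by the pre-offset ramp at
#'   offset.
#' @param offset_ramp_len Length (s) of the pre-offset ramp.
#' @param motion_amp Standard deviation (a.u.) of the shared motion artifact.
#' @param motion_band Pass band (Hz, pair) of the artifact's shaping filter.
#'   Motion artifacts are band-limited jerks: slow drift belongs to
#'   bleaching, so the band excludes near-DC components, and it stays below
#'   the reference low-pass corner (3 Hz) so referencing can see it.
#' @param motion_gain_signal,motion_gain_ref Per-channel artifact coupling
#'   gains.
#' @param noise_sd Per-sample Gaussian noise SD (a.u.) of the signal
#'   channel (and, by default, the reference).
#' @param ref_noise_sd Reference-channel noise SD (a.u.); NULL (default)
#'   uses \code{noise_sd}. Reference noise that is large relative to the
#'   bleaching spread attenuates the stimulation-mode referencing regression
#'   (errors-in-variables), so rigs-with-quiet-references are modeled by
#'   setting this independently.
#' @param ref_frac Reference-channel fluorescence as a fraction of the
#'   signal channel's bleaching curve.
#' @param bout_rate Locomotion bouts per minute.
#' @param bout_dur_mean Mean bout duration (s).
#' @param bout_vel_mean Mean bout plateau velocity (cm/s); treadmill mice
#'   walk slowly, so the default is 3 cm/s.
#' @param elevation_amp,suppression_amp,rebound_amp Stimulation-response
#'   amplitudes in dF/F fraction units (suppression entered positive; the
#'   generated response is negative-going).
#' @param rebound_tau Rebound decay time constant (s).
#' @param seed Optional integer seed.
#' @return Object of class \code{synth_config}.
#' @export
synth_config <- function(duration = 1800, rate = 1000,
                         baseline_F = 1.0, bleach_amp = 0.3,
                         bleach_tau = 600,
                         rise_tau = 0.05, decay_tau = 0.5,
                         transient_amp = 0.06,
                         event_lag = -0.15, offset_slope_sign = -1,
                         offset_ramp_amp = 0.02, offset_ramp_len = 1.5,
                         motion_amp = 0.014, motion_band = c(0.8, 2.2),
                         motion_gain_signal = 1.0, motion_gain_ref = 0.9,
                         noise_sd = 0.003, ref_noise_sd = NULL,
                         ref_frac = 0.8,
                         bout_rate = 1, bout_dur_mean = 2,
                         bout_vel_mean = 3,
                         elevation_amp = 0, suppression_amp = 0.02,
                         rebound_amp = 0.01, rebound_tau = 5,
                         seed = NULL) {
  cfg <- as.list(environment())
  if (duration <= 0 || rate <= 0) sf_param_error("duration and rate must be > 0")
  if (rise_tau <= 0 || decay_tau <= 0 || bleach_tau <= 0 || rebound_tau <= 0)
    sf_param_error("all time constants must be > 0")
  if (noise_sd < 0 || motion_amp < 0) sf_param_error("noise/motion SDs must be >= 0")
  if (!offset_slope_sign %in% c(-1, 1))
    sf_param_error("offset_slope_sign must be +1 or -1")
  if (bleach_amp >= baseline_F)
    sf_param_error("bleach_amp must stay below baseline_F (F must remain positive)")
  structure(cfg, class = "synth_config")
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

# rest-period jitter stays below half the default movement threshold
# (0.25 cm/s) so segmentation ground truth is unambiguous
REST_JITTER_CAP <- 0.12
BOUT_FLOOR_VEL <- 0.3   # in-bout velocity never drops below this (cm/s)

#' Simulate bout-structured locomotion
#'
#' Generates a zero-inflated treadmill velocity trace: rest periods of small
#' jitter (capped at 0.12 cm/s, below half the movement threshold) alternate
#' with walking bouts whose velocity ramps up and down smoothly (raised
#' cosine, 0.3 s) around a plateau near \code{bout_vel_mean}, never dipping
#' below 0.3 cm/s inside a bout. Bout onsets follow a Poisson process of
#' rate \code{bout_rate}/min thinned by a 1.5-s refractory gap; durations are
#' gamma-distributed (shape 4) with mean \code{bout_dur_mean}, floored at
#' 0.8 s. The returned bout table is the exact ground-truth segmentation:
#' every in-bout sample exceeds the movement threshold and every rest sample
#' stays below it.
#'
#' @param config A [synth_config()].
#' @return List with \code{track} (a [behavior_track()]) and \code{bouts}
#'   (ground-truth bout table, kind "movement").
#' @export
simulate_locomotion <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    rate <- config$rate
    n <- round(config$duration * rate)
    t <- (seq_len(n) - 1) / rate
    v <- pmin(abs(rnorm(n, 0, 0.04)), REST_JITTER_CAP)

    expected <- config$bout_rate * config$duration / 60
    if (expected < 1)
      warning(sprintf("fewer than one bout expected (%.2f); bout table may be empty",
                      expected), call. = FALSE)

    onsets <- offsets <- mv <- numeric(0)
    if (config$bout_rate > 0) {
      margin <- 2; min_gap <- 1.5
      cur <- margin + rexp(1, config$bout_rate / 60)
      repeat {
        dur_b <- max(0.8, rgamma(1, shape = 4, scale = config$bout_dur_mean / 4))
        if (cur + dur_b > config$duration - margin) break
        io <- round(cur * rate) + 1
        ne <- max(round(dur_b * rate), round(0.8 * rate))
        ie <- min(io + ne - 1, n)
        nb <- ie - io + 1
        env <- rep(1, nb)
        rs <- min(round(0.3 * rate), floor(nb / 2))
        if (rs > 0) {
          ramp <- (1 - cos(pi * seq_len(rs) / rs)) / 2
          env[seq_len(rs)] <- ramp
          env[nb + 1 - seq_len(rs)] <- ramp
        }
        amp <- max(config$bout_vel_mean * exp(rnorm(1, 0, 0.2)), 1.2)
        vb <- BOUT_FLOOR_VEL + (amp - BOUT_FLOOR_VEL) * env
        vb <- pmax(vb * (1 + 0.05 * rnorm(nb)), BOUT_FLOOR_VEL - 0.03)
        v[io:ie] <- vb
        onsets <- c(onsets, t[io])
        offsets <- c(offsets, t[ie] + 1 / rate)
        mv <- c(mv, mean(vb))
        cur <- (cur + dur_b) + min_gap + rexp(1, config$bout_rate / 60)
      }
    }
    list(track = behavior_track(t, v, sample_rate = rate),
         bouts = new_bout_table(onsets, offsets, mv,
                                rep("movement", length(onsets))))
  })
}

#' Motion index from velocity
#'
#' Saturating map from velocity to a normalized motion index in [0, 1],
#' standing in for the video pixel-change metric the open-field assay uses:
#' \code{v / (v + v_half)}.
#'
#' @param velocity Velocity (cm/s), non-negative.
#' @param v_half Velocity (cm/s) at which the index reaches 0.5.
#' @return Motion index in [0, 1].
#' @export
motion_index_from_velocity <- function(velocity, v_half = 2) {
  v <- pmax(velocity, 0)
  v / (v + v_half)
}

bleach_curve <- function(config, t) {
  config$baseline_F - config$bleach_amp * (1 - exp(-t / config$bleach_tau))
}

transient_kernel <- function(config, rate) {
  tk <- seq(0, 6 * config$decay_tau, by = 1 / rate)
  k <- (1 - exp(-tk / config$rise_tau)) * exp(-tk / config$decay_tau)
  k / max(k) * config$transient_amp
}

#' Simulate a photometry session locked to locomotion
#'
#' Builds signal and reference channels on the behavior timebase:
#' \itemize{
#'   \item both channels share an exponential bleaching curve (the reference
#'     scaled by \code{ref_frac}) and a low-pass-filtered Gaussian motion
#'     artifact coupled with per-channel gains;
#'   \item the signal channel additionally carries double-exponential
#'     transients placed at bout onset + \code{event_lag} and a linear ramp
#'     into each bout offset whose direction is \code{offset_slope_sign}
#'     (the ramp relaxes exponentially after offset);
#'   \item the reference carries no transient component whatsoever -- the
#'     isosbestic contract -- so any "activity" recovered from it downstream
#'     is an artifact of the pipeline.
#' }
#'
#' @param config A [synth_config()].
#' @param behavior A [behavior_track()] from [simulate_locomotion()].
#' @param true_bouts Its ground-truth bout table.
#' @return List with \code{session} (a [photometry_session()]) and
#'   \code{truth}: event times, true lag, true pre-offset slope (a.u./s),
#'   the artifact trace, the transient-only trace and the bleaching curve.
#' @export
simulate_photometry <- function(config, behavior, true_bouts) {
  stopifnot(inherits(config, "synth_config"),
            inherits(behavior, "behavior_track"))
  seed <- if (is.null(config$seed)) NULL else config$seed + 1
  with_seed(seed, {
    t <- behavior$t
    rate <- behavior$sample_rate
    n <- length(t)
    bleach <- bleach_curve(config, t)

    # transients at bout onset + lag
    trans <- numeric(n)
    kern <- transient_kernel(config, rate)
    ev <- true_bouts$onset + config$event_lag
    ev <- ev[ev >= t[1] & ev <= t[n]]
    for (e in ev) {
      i0 <- round((e - t[1]) * rate) + 1
      i1 <- min(i0 + length(kern) - 1, n)
      if (i0 >= 1 && i0 <= n)
        trans[i0:i1] <- trans[i0:i1] + kern[seq_len(i1 - i0 + 1)]
    }

    # pre-offset activity trend: fluorescence stays non-negative relative to
    # baseline, so a "decreasing" trend (-1) is an elevated level decaying to
    # zero at offset, and an "increasing" trend (+1) ramps from zero up to
    # `offset_ramp_amp` at offset and relaxes exponentially afterwards
    ramp_tr <- numeric(n)
    amp <- config$offset_ramp_amp
    for (j in seq_len(nrow(true_bouts))) {
      off <- true_bouts$offset[j]
      on <- true_bouts$onset[j]
      a <- max(off - config$offset_ramp_len, on)
      idx <- window_idx(t, a, off)
      frac <- (t[idx] - a) / (off - a)
      if (config$offset_slope_sign > 0) {
        if (length(idx) > 1) ramp_tr[idx] <- ramp_tr[idx] + amp * frac
        post <- window_idx(t, off, min(off + 3, t[n] + 1 / rate))
        if (length(post) > 0)
          ramp_tr[post] <- ramp_tr[post] + amp * exp(-(t[post] - off) / 0.5)
      } else {
        if (length(idx) > 1) ramp_tr[idx] <- ramp_tr[idx] + amp * (1 - frac)
        # plateau (with a short lead-in ramp) between onset and the decay
        pre <- window_idx(t, on, a)
        if (length(pre) > 0) {
          lead <- pmin((t[pre] - on) / 0.3, 1)
          ramp_tr[pre] <- ramp_tr[pre] + amp * lead
        }
      }
    }

    # shared artifact: always drawn (fixed RNG consumption), scaled by gain
    raw <- rnorm(n)
    art <- if (config$motion_amp > 0) {
      bf <- signal::butter(2, config$motion_band / (rate / 2), type = "pass")
      f <- as.numeric(signal::filtfilt(bf, raw))
      f / stats::sd(f) * config$motion_amp
    } else numeric(n)

    noise_s <- rnorm(n, 0, 1) * config$noise_sd
    noise_r <- rnorm(n, 0, 1) * (config$ref_noise_sd %||% config$noise_sd)
    sig <- bleach + trans + ramp_tr + config$motion_gain_signal * art + noise_s
    ref <- config$ref_frac * bleach + config$motion_gain_ref * art + noise_r

    events <- tibble::tibble(
      timestamp = c(true_bouts$onset, true_bouts$offset),
      label = rep(c("locomotion_onset", "locomotion_offset"),
                  each = nrow(true_bouts)))
    events <- events[order(events$timestamp), , drop = FALSE]

    list(
      session = photometry_session(t, sig, ref, sample_rate = rate,
                                   events = events),
      truth = list(
        event_times = ev,
        true_event_lag = config$event_lag,
        true_offset_slope = amp / config$offset_ramp_len,
        artifact = art,
        transient_trace = trans,
        ramp_trace = ramp_tr,
        bleach = bleach
      )
    )
  })
}

#' Simulate a treadmill photometry session
#'
#' Convenience wrapper chaining [simulate_locomotion()] and
#' [simulate_photometry()] into a [session_bundle()] with ground truth.
#'
#' @param config A [synth_config()].
#' @return List with \code{bundle} and \code{truth} (including
#'   \code{true_bouts}).
#' @export
simulate_treadmill_session <- function(config) {
  loco <- simulate_locomotion(config)
  phot <- simulate_photometry(config, loco$track, loco$bouts)
  truth <- phot$truth
  truth$true_bouts <- loco$bouts
  list(bundle = session_bundle(photometry = phot$session,
                               behavior = loco$track,
                               subject_id = "synthetic"),
       truth = truth)
}

# noiseless stimulation response in dF/F fraction units, sampled on `tl`
# (lags relative to trial onset): elevation boxcar over [0.3, 1.2) s
# post-onset; suppression ramp from min(1.5, dur/2) reaching -suppression at
# the offset sample (inclusive); rebound strictly after offset.
stim_response_shape <- function(config, tl, dur) {
  resp <- numeric(length(tl))
  resp[tl >= 0.3 - .sf_tol & tl < 1.2 - .sf_tol] <- config$elevation_amp
  rs <- min(1.5, dur / 2)
  in_ramp <- tl >= rs - .sf_tol & tl <= dur + .sf_tol
  resp[in_ramp] <- resp[in_ramp] -
    config$suppression_amp * (tl[in_ramp] - rs) / (dur - rs)
  post <- tl > dur + .sf_tol
  resp[post] <- resp[post] +
    config$rebound_amp * exp(-(tl[post] - dur) / config$rebound_tau)
  resp
}

#' Simulate an optogenetic-stimulation photometry session
#'
#' Generates a sensor trace around a stimulation protocol: per trial, the
#' fractional response is an elevation boxcar (0.3-1.2 s post-onset), a
#' linear suppression ramp reaching \code{-suppression_amp} at offset, and a
#' post-offset exponential rebound; the raw signal is the bleaching curve
#' times (1 + response) plus noise, and the reference is the scaled bleaching
#' curve plus noise (no response -- isosbestic contract). Ground truth
#' includes both the constructed amplitudes and the noiseless per-duration
#' expectation of each analysis window, computed directly from the response
#' shape on the sampling grid.
#'
#' @param config A [synth_config()].
#' @param protocol A [stim_protocol()]; every trial needs at least 10 s of
#'   margin inside the session.
#' @return List with \code{bundle} (photometry + stim) and \code{truth}:
#'   amplitudes and a per-duration tibble of expected
#'   (initial_elevation, max_reduction, post_stim_change).
#' @export
simulate_stim_session <- function(config, protocol) {
  stopifnot(inherits(config, "synth_config"),
            inherits(protocol, "stim_protocol"))
  offs <- protocol$trial_onsets + protocol$trial_durations
  if (any(protocol$trial_onsets < 10) || any(offs + 10 > config$duration))
    sf_param_error("every stimulation trial needs >= 10 s margins inside the session")
  seed <- if (is.null(config$seed)) NULL else config$seed + 2
  with_seed(seed, {
    rate <- config$rate
    n <- round(config$duration * rate)
    t <- (seq_len(n) - 1) / rate
    bleach <- bleach_curve(config, t)
    resp <- numeric(n)
    for (i in seq_along(protocol$trial_onsets)) {
      on <- protocol$trial_onsets[i]
      dur <- protocol$trial_durations[i]
      idx <- window_idx(t, on, min(on + dur + 9.5, t[n] + 1 / rate))
      resp[idx] <- resp[idx] + stim_response_shape(config, t[idx] - on, dur)
    }
    sig <- bleach * (1 + resp) + rnorm(n, 0, 1) * config$noise_sd
    ref <- config$ref_frac * bleach +
      rnorm(n, 0, 1) * (config$ref_noise_sd %||% config$noise_sd)

    expected <- expected_stim_metrics(config, protocol, rate)
    bundle <- session_bundle(
      photometry = photometry_session(
        t, sig, ref, sample_rate = rate, signal_wavelength = 560,
        events = tibble::tibble(timestamp = protocol$trial_onsets,
                                label = "stim_onset")),
      stim = protocol, subject_id = "synthetic")
    list(bundle = bundle,
         truth = list(elevation_amp = config$elevation_amp,
                      suppression_amp = config$suppression_amp,
                      rebound_amp = config$rebound_amp,
                      rebound_tau = config$rebound_tau,
                      response_trace = resp,
                      expected = expected))
  })
}

#' Expected stimulation metrics of the synthetic response shape
#'
#' Noiseless per-duration expectation of the three analysis windows, computed
#' directly from the generator's response shape on the sampling grid (mean
#' over 0.5-1 s post-onset; minimum over the 1 s before offset; mean over
#' 4-9 s post-offset).
#'
#' @param config A [synth_config()].
#' @param protocol A [stim_protocol()].
#' @param rate Sampling rate (Hz).
#' @return Tibble: stim_duration, initial_elevation, max_reduction,
#'   post_stim_change (dF/F fractions).
#' @export
expected_stim_metrics <- function(config, protocol, rate = config$rate) {
  durs <- sort(unique(protocol$trial_durations))
  do.call(rbind, lapply(durs, function(dur) {
    tl <- seq(-1, dur + 9.5, by = 1 / rate)
    resp <- stim_response_shape(config, tl, dur)
    elev <- mean(resp[tl >= 0.5 - .sf_tol & tl < 1 - .sf_tol])
    red <- min(resp[tl >= dur - 1 - .sf_tol & tl < dur - .sf_tol])
    post <- mean(resp[tl >= dur + 4 - .sf_tol & tl < dur + 9 - .sf_tol])
    tibble::tibble(stim_duration = dur, initial_elevation = elev,
                   max_reduction = red, post_stim_change = post)
  }))
}

#' Simulate event-aligned activity trials
#'
#' Directly generates an aligned trial matrix with known structure, for
#' testing the timing metrics without building full sessions:
#' \describe{
#'   \item{step}{activity jumps by \code{amplitude} z-units at
#'     \code{true_lag} (rise-time recovery).}
#'   \item{ramp}{activity is a line of slope \code{amplitude} z-units/s
#'     through lag 0 (pre-offset slope recovery).}
#'   \item{bump}{a Gaussian bump of SD \code{bump_sd} centered at
#'     \code{true_lag} (peak-time recovery).}
#' }
#' Independent Gaussian noise of SD \code{noise_sd} is added per sample and
#' trial.
#'
#' @param n_trials Number of trials.
#' @param true_lag Event lag (s) of the feature.
#' @param amplitude Step/bump amplitude (z-units) or ramp slope (z-units/s).
#' @param noise_sd Per-sample noise SD (z-units).
#' @param rate Sampling rate (Hz).
#' @param window Lag window (s).
#' @param shape "step", "ramp" or "bump".
#' @param bump_sd Gaussian bump SD (s).
#' @param anchor Anchor label for the matrix.
#' @param seed Optional seed.
#' @return An \code{aligned_matrix}.
#' @export
simulate_aligned_trials <- function(n_trials, true_lag = -0.15,
                                    amplitude = 1, noise_sd = 0.3,
                                    rate = 1000, window = c(-1, 0.5),
                                    shape = c("step", "ramp", "bump"),
                                    bump_sd = 0.1,
                                    anchor = c("onset", "offset"),
                                    seed = NULL) {
  shape <- match.arg(shape)
  anchor <- match.arg(anchor)
  with_seed(seed, {
    lags <- seq(round(window[1] * rate), round(window[2] * rate)) / rate
    nl <- length(lags)
    base <- switch(shape,
      step = amplitude * (lags >= true_lag - .sf_tol),
      ramp = amplitude * lags,
      bump = amplitude * exp(-(lags - true_lag)^2 / (2 * bump_sd^2)))
    mat <- matrix(rnorm(n_trials * nl, 0, noise_sd), nrow = n_trials,
                  byrow = TRUE)
    mat <- sweep(mat, 2, base, `+`)
    structure(list(lags = lags, mat = mat, anchor = anchor,
                   trial_ids = seq_len(n_trials)),
              class = "aligned_matrix")
  })
}
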