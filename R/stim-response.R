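# Stimulation-locked response quantification: per-trial baseline-subtracted
# dF/F windows and the three summary amplitudes (initial elevation, maximal
# reduction, post-stimulation change), plus epoch-wise velocity summaries for
# the 3-min ON/OFF open-field design. Sign convention: suppression is
# negative throughout.

#' Extract baseline-subtracted stimulation trials
#'
#' Cuts a dF/F trace into per-trial windows spanning \code{[-5, duration + 9]}
#' s around each stimulation onset and subtracts each trial's own baseline,
#' the mean dF/F over the 5 s preceding onset. Trials without the full
#' pre/post margin inside the session are dropped with a message.
#'
#' @param norm A \code{normalized_trace} (with its \code{t} field set) or a
#'   plain list with fields \code{t} and \code{dff}.
#' @param protocol A [stim_protocol()].
#' @param params [analysis_params()].
#' @return List of \code{stim_trial_window} objects, each with
#'   \code{trial_index}, \code{lags} (s, relative to onset), \code{dff}
#'   (baseline-subtracted), \code{stim_duration} and \code{baseline}
#'   (the subtracted mean).
#' @export
extract_stim_trials <- function(norm, protocol, params = analysis_params()) {
  stopifnot(inherits(protocol, "stim_protocol"))
  t <- norm$t
  dff <- norm$dff
  if (is.null(t) || length(t) != length(dff))
    sf_schema_error("normalized trace needs a time grid matching dff")
  rate <- 1 / (t[2] - t[1])
  pre <- params$stim_baseline_window
  post <- params$stim_post_window[2]
  trials <- list()
  dropped <- 0L
  for (i in seq_along(protocol$trial_onsets)) {
    on <- protocol$trial_onsets[i]
    dur <- protocol$trial_durations[i]
    k1 <- round(-pre * rate)
    k2 <- round((dur + post) * rate)
    ie <- round((on - t[1]) * rate) + 1
    if (ie + k1 < 1 || ie + k2 > length(dff)) {
      dropped <- dropped + 1L
      next
    }
    lags <- (k1:k2) / rate
    seg <- dff[(ie + k1):(ie + k2)]
    bl_idx <- window_idx(lags, -pre, 0)
    bl <- mean(seg[bl_idx])
    trials[[length(trials) + 1]] <- structure(
      list(trial_index = i, lags = lags, dff = seg - bl,
           stim_duration = dur, baseline = bl),
      class = "stim_trial_window")
  }
  if (dropped > 0)
    message(sprintf("extract_stim_trials: dropped %d trial(s) without full margins",
                    dropped))
  trials
}

check_window_contained <- function(trial, a, b, what) {
  lags <- trial$lags
  if (a < min(lags) - .sf_tol || b > max(lags) + 1e-9 + .sf_tol)
    sf_timing_error(sprintf(
      "%s window [%.3f, %.3f) s lies outside the trial extent [%.3f, %.3f] s",
      what, a, b, min(lags), max(lags)))
  idx <- window_idx(lags, a, b)
  if (length(idx) == 0)
    sf_timing_error(sprintf("%s window [%.3f, %.3f) s contains no samples",
                            what, a, b))
  idx
}

#' Initial elevation of the stimulation response
#'
#' Mean baseline-subtracted dF/F over the 0.5-s interval 0.5-1 s after
#' stimulus onset, the window capturing the transient dopamine surge at
#' stimulation onset.
#'
#' @param trial A \code{stim_trial_window}.
#' @param params [analysis_params()].
#' @return Mean dF/F over the elevation window.
#' @export
initial_elevation <- function(trial, params = analysis_params()) {
  w <- params$stim_elevation_window
  idx <- check_window_contained(trial, w[1], w[2], "elevation")
  mean(trial$dff[idx])
}

#' Maximal reduction of the stimulation response
#'
#' Lowest baseline-subtracted dF/F value within the 1-s interval before
#' stimulus offset: the peak suppression reached during stimulation
#' (negative when the signal is suppressed). Note that on a flat noisy trial
#' the minimum of a window is biased below zero (an order-statistic
#' property); compare against matched control trials or noiseless ground
#' truth accordingly.
#'
#' @param trial A \code{stim_trial_window}.
#' @param params [analysis_params()].
#' @return Minimum dF/F over the pre-offset window.
#' @export
max_reduction <- function(trial, params = analysis_params()) {
  dur <- trial$stim_duration
  w <- params$stim_reduction_window
  idx <- check_window_contained(trial, dur - w, dur, "reduction")
  min(trial$dff[idx])
}

#' Post-stimulation change
#'
#' Mean baseline-subtracted dF/F over the 5-s interval spanning 4-9 s after
#' stimulus offset, the window capturing rebound release after the end of
#' stimulation.
#'
#' @param trial A \code{stim_trial_window}.
#' @param params [analysis_params()].
#' @return Mean dF/F over the post-stimulation window.
#' @export
post_stim_change <- function(trial, params = analysis_params()) {
  dur <- trial$stim_duration
  w <- params$stim_post_window
  idx <- check_window_contained(trial, dur + w[1], dur + w[2], "post-stimulation")
  mean(trial$dff[idx])
}

#' Summarize stimulation responses per trial and per duration group
#'
#' Computes the three response amplitudes for every trial and averages them
#' within stimulation-duration groups (trials of different durations are
#' summarized separately, since all windows are offset-anchored). Set
#' \code{mean_trace = TRUE} to compute the metrics on the trial-mean trace of
#' each duration group instead of per trial (the per-trial minimum is biased
#' by noise; the mean-trace mode trades that bias for fewer observations).
#'
#' @param trials List of \code{stim_trial_window} from
#'   [extract_stim_trials()].
#' @param params [analysis_params()].
#' @param mean_trace Compute metrics on the per-duration mean trace.
#' @return List with \code{per_trial} (tibble: trial_index, stim_duration,
#'   initial_elevation, max_reduction, post_stim_change) and
#'   \code{per_duration} (tibble of group means and n).
#' @export
stim_response_summary <- function(trials, params = analysis_params(),
                                  mean_trace = FALSE) {
  if (length(trials) == 0) sf_input_error("no stimulation trials to summarize")
  per_trial <- do.call(rbind, lapply(trials, function(tr) {
    tibble::tibble(trial_index = tr$trial_index,
                   stim_duration = tr$stim_duration,
                   initial_elevation = initial_elevation(tr, params),
                   max_reduction = max_reduction(tr, params),
                   post_stim_change = post_stim_change(tr, params))
  }))
  durs <- sort(unique(per_trial$stim_duration))
  per_duration <- do.call(rbind, lapply(durs, function(d) {
    if (mean_trace) {
      grp <- trials[vapply(trials, function(tr) tr$stim_duration == d,
                           logical(1))]
      lags <- grp[[1]]$lags
      m <- colMeans(do.call(rbind, lapply(grp, `[[`, "dff")))
      mt <- structure(list(lags = lags, dff = m, stim_duration = d),
                      class = "stim_trial_window")
      tibble::tibble(stim_duration = d, n_trials = length(grp),
                     initial_elevation = initial_elevation(mt, params),
                     max_reduction = max_reduction(mt, params),
                     post_stim_change = post_stim_change(mt, params))
    } else {
      sub <- per_trial[per_trial$stim_duration == d, ]
      tibble::tibble(stim_duration = d, n_trials = nrow(sub),
                     initial_elevation = mean(sub$initial_elevation),
                     max_reduction = mean(sub$max_reduction),
                     post_stim_change = mean(sub$post_stim_change))
    }
  }))
  list(per_trial = per_trial, per_duration = per_duration)
}

#' Epoch-wise velocity summary for the 3-min ON/OFF design
#'
#' Splits an open-field session into the canonical epochs of the 3-min
#' stimulation design -- prior (3 min before the first stimulation), each ON
#' epoch, 1st OFF (3 min after the first stimulation) and 2nd OFF (3 min
#' after the second) -- and reports per-epoch mean velocity, the velocity
#' ratio normalized to the prior epoch, and ambulation/immobility bout
#' summaries. Bouts are clipped at epoch boundaries and counted in the epoch
#' containing their onset, which keeps frequencies additive across epochs.
#'
#' @param track A [behavior_track()].
#' @param protocol A [stim_protocol()] with \code{schedule_kind}
#'   "epoch_3min" and at least two trials.
#' @param params [analysis_params()].
#' @param ambulation,immobility Optional pre-computed bout tables; computed
#'   from \code{track} when omitted (immobility only if a motion index is
#'   present).
#' @return Tibble with one row per epoch: epoch, t_start, t_end,
#'   mean_velocity, velocity_ratio, ambulation and immobility summary
#'   columns.
#' @export
epoch_velocity_summary <- function(track, protocol,
                                   params = analysis_params(),
                                   ambulation = NULL, immobility = NULL) {
  stopifnot(inherits(track, "behavior_track"),
            inherits(protocol, "stim_protocol"))
  if (protocol$schedule_kind != "epoch_3min")
    sf_param_error("epoch summaries apply to the epoch_3min schedule")
  if (length(protocol$trial_onsets) < 2)
    sf_param_error("need at least two stimulation epochs")
  on <- protocol$trial_onsets
  dur <- protocol$trial_durations
  ep_len <- dur[1]
  epochs <- tibble::tibble(
    epoch = c("prior", "on1", "off1", "on2", "off2"),
    t_start = c(on[1] - ep_len, on[1], on[1] + dur[1], on[2], on[2] + dur[2]),
    t_end = c(on[1], on[1] + dur[1], on[2], on[2] + dur[2],
              on[2] + dur[2] + ep_len)
  )
  t0 <- track$t[1]; t1 <- track$t[length(track$t)] + 1 / track$sample_rate
  if (epochs$t_start[1] < t0 - .sf_tol || epochs$t_end[5] > t1 + .sf_tol)
    sf_timing_error("epoch schedule extends outside the recording")

  if (is.null(ambulation)) ambulation <- detect_ambulation_bouts(track, params)
  if (is.null(immobility) && !is.null(track$motion_index))
    immobility <- detect_immobility_bouts(track, params)

  clip_bouts <- function(bouts, a, b) {
    if (is.null(bouts) || nrow(bouts) == 0) return(bouts)
    sel <- bouts$onset >= a - .sf_tol & bouts$onset < b - .sf_tol
    cl <- bouts[sel, , drop = FALSE]
    cl$offset <- pmin(cl$offset, b)
    cl$duration <- cl$offset - cl$onset
    cl
  }

  rows <- lapply(seq_len(nrow(epochs)), function(i) {
    a <- epochs$t_start[i]; b <- epochs$t_end[i]
    idx <- window_idx(track$t, a, b)
    amb <- clip_bouts(ambulation, a, b)
    amb_s <- bout_summary(amb, b - a)
    out <- tibble::tibble(
      epoch = epochs$epoch[i], t_start = a, t_end = b,
      mean_velocity = mean(track$velocity[idx]),
      ambulation_pct = amb_s$pct_time,
      ambulation_freq = amb_s$freq_per_min,
      ambulation_dur = amb_s$mean_dur
    )
    if (!is.null(immobility)) {
      imm <- clip_bouts(immobility, a, b)
      imm_s <- bout_summary(imm, b - a)
      out$immobility_freq <- imm_s$freq_per_min
      out$immobility_dur <- imm_s$mean_dur
    }
    out
  })
  out <- do.call(rbind, rows)
  prior <- out$mean_velocity[out$epoch == "prior"]
  if (prior == 0)
    sf_numeric_error("prior-epoch mean velocity is zero; velocity ratio undefined")
  out$velocity_ratio <- out$mean_velocity / prior
  out[, c("epoch", "t_start", "t_end", "mean_velocity", "velocity_ratio",
          setdiff(names(out), c("epoch", "t_start", "t_end", "mean_velocity",
                                "velocity_ratio")))]
}
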