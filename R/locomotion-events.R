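# Bout segmentation for the three assay-specific rule sets (treadmill
# movement, open-field ambulation, open-field immobility) plus trial-state
# classification around stimulation events.
#
# Conventions shared by every detector:
#  * comparisons against thresholds are strict, mirroring the printed
#    inequalities; a sample exactly at threshold belongs to neither class and
#    breaks runs;
#  * bout intervals are half-open [onset, offset) in seconds, with boundaries
#    reported at the first sample of the new state (no sub-sample
#    interpolation).

# time tolerance for half-open window membership on a uniform grid
.sf_tol <- 1e-6

window_idx <- function(t, a, b) {
  which(t >= a - .sf_tol & t < b - .sf_tol)
}

# run-length structure over a 3-state coding: 1 = above/"in", 0 = below/"out",
# -1 = exactly at threshold (breaks runs, belongs to neither)
state_runs <- function(state) {
  r <- rle(state)
  ends <- cumsum(r$lengths)
  tibble::tibble(value = r$values,
                 start = ends - r$lengths + 1L,
                 end = ends,
                 length = r$lengths)
}

new_bout_table <- function(onset = numeric(0), offset = numeric(0),
                           mean_velocity = numeric(0),
                           kind = character(0)) {
  tibble::tibble(onset = onset, offset = offset,
                 duration = offset - onset,
                 mean_velocity = mean_velocity, kind = kind)
}

#' Detect treadmill movement bouts
#'
#' Segments a treadmill velocity trace into movement bouts. Time bins are
#' binarized at \code{move_threshold} (0.25 cm/s); sub-threshold runs count
#' as rest only when longer than \code{min_rest_dur} (0.8 s) -- shorter ones
#' are absorbed into the surrounding movement; movement periods shorter than
#' \code{min_move_dur} (0.5 s) or with mean velocity below
#' \code{min_move_mean_vel} (0.5 cm/s) are excluded. A bout's onset is the
#' threshold crossing that ends a valid rest period and its offset the
#' crossing followed by a valid rest period, so bouts touching the session
#' edges are not scored.
#'
#' The relative order of the absorb and filter steps is not dictated by the
#' rules themselves; the default applies absorption first (onset/offset are
#' defined relative to valid rest periods), with the alternative available
#' via \code{params$treadmill_rule_order = "filter_first"}.
#'
#' @param track A [behavior_track()] on a uniform grid.
#' @param params [analysis_params()].
#' @return Bout table: tibble with columns onset, offset, duration (s),
#'   mean_velocity (cm/s), kind = "movement".
#' @export
detect_treadmill_bouts <- function(track, params = analysis_params()) {
  stopifnot(inherits(track, "behavior_track"))
  v <- track$velocity
  t <- track$t
  rate <- track$sample_rate
  thr <- params$move_threshold
  state <- ifelse(v > thr, 1L, ifelse(v < thr, 0L, -1L))

  absorb <- function(state) {
    runs <- state_runs(state)
    short_rest <- runs$value == 0L & runs$length / rate <= params$min_rest_dur
    for (i in which(short_rest)) {
      prev_move <- i > 1 && runs$value[i - 1] == 1L
      next_move <- i < nrow(runs) && runs$value[i + 1] == 1L
      if (prev_move || next_move)
        state[runs$start[i]:runs$end[i]] <- 1L
    }
    state
  }
  filter_moves <- function(state) {
    runs <- state_runs(state)
    for (i in which(runs$value == 1L)) {
      dur <- runs$length[i] / rate
      mv <- mean(v[runs$start[i]:runs$end[i]])
      if (dur < params$min_move_dur || mv < params$min_move_mean_vel)
        state[runs$start[i]:runs$end[i]] <- -1L
    }
    state
  }

  if (params$treadmill_rule_order == "absorb_first") {
    state <- filter_moves(absorb(state))
  } else {
    state <- absorb(filter_moves(state))
  }

  runs <- state_runs(state)
  valid_rest <- runs$value == 0L & runs$length / rate > params$min_rest_dur
  keep <- integer(0)
  for (i in which(runs$value == 1L)) {
    ok_pre <- i > 1 && valid_rest[i - 1]
    ok_post <- i < nrow(runs) && valid_rest[i + 1]
    if (ok_pre && ok_post) keep <- c(keep, i)
  }
  if (length(keep) == 0) return(new_bout_table())
  onset <- t[runs$start[keep]]
  # offset = first sample of the following rest run (half-open interval)
  offset <- t[runs$end[keep]] + 1 / rate
  mv <- vapply(keep, function(i) mean(v[runs$start[i]:runs$end[i]]),
               numeric(1))
  new_bout_table(onset, offset, mv, rep("movement", length(keep)))
}

# shared machinery for ambulation/immobility: take a logical "in-state" mask,
# merge in-state runs separated by gaps <= min_sep, drop merged runs with
# duration <= min_dur (strict "lasting for > min_dur")
merge_filter_mask <- function(mask, t, rate, min_dur, min_sep) {
  runs <- state_runs(ifelse(mask, 1L, 0L))
  ins <- which(runs$value == 1L)
  if (length(ins) == 0)
    return(tibble::tibble(start = integer(0), end = integer(0)))
  # merge across short gaps
  start <- runs$start[ins]
  end <- runs$end[ins]
  m_start <- start[1]
  m_end <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  if (length(ins) > 1) {
    for (k in 2:length(ins)) {
      gap <- (start[k] - m_end - 1L) / rate
      if (gap <= min_sep) {
        m_end <- end[k]
      } else {
        out_s <- c(out_s, m_start); out_e <- c(out_e, m_end)
        m_start <- start[k]; m_end <- end[k]
      }
    }
  }
  out_s <- c(out_s, m_start); out_e <- c(out_e, m_end)
  dur <- (out_e - out_s + 1L) / rate
  keep <- dur > min_dur
  tibble::tibble(start = out_s[keep], end = out_e[keep])
}

#' Detect open-field ambulation bouts
#'
#' Ambulation bouts are periods of movement above
#' \code{ambulation_threshold} (2 cm/s) lasting more than
#' \code{ambulation_min_dur} (0.5 s); supra-threshold runs separated by gaps
#' of at most \code{ambulation_min_sep} (0.5 s) are merged first, so
#' "separated by more than 0.5 s" is what keeps bouts distinct.
#'
#' @param track A [behavior_track()].
#' @param params [analysis_params()].
#' @return Bout table with kind = "ambulation".
#' @export
detect_ambulation_bouts <- function(track, params = analysis_params()) {
  stopifnot(inherits(track, "behavior_track"))
  v <- track$velocity; t <- track$t; rate <- track$sample_rate
  seg <- merge_filter_mask(v > params$ambulation_threshold, t, rate,
                           params$ambulation_min_dur,
                           params$ambulation_min_sep)
  if (nrow(seg) == 0) return(new_bout_table())
  onset <- t[seg$start]
  offset <- t[seg$end] + 1 / rate
  mv <- mapply(function(s, e) mean(v[s:e]), seg$start, seg$end)
  new_bout_table(onset, offset, as.numeric(mv),
                 rep("ambulation", nrow(seg)))
}

#' Detect open-field immobility bouts
#'
#' Immobility bouts are periods where the normalized motion index (video
#' pixel-change proxy) stays below \code{immobility_threshold} (0.02, i.e.
#' <2\% pixel change) for more than 0.5 s, with sub-threshold runs separated
#' by at most 0.5 s merged, mirroring the ambulation machinery on the
#' complementary state.
#'
#' @param track A [behavior_track()] whose \code{motion_index} is present.
#' @param params [analysis_params()].
#' @return Bout table with kind = "immobility"; \code{mean_velocity} is
#'   taken from the velocity trace.
#' @export
detect_immobility_bouts <- function(track, params = analysis_params()) {
  stopifnot(inherits(track, "behavior_track"))
  if (is.null(track$motion_index))
    sf_input_error("immobility detection needs a motion_index trace")
  mi <- track$motion_index; t <- track$t; rate <- track$sample_rate
  seg <- merge_filter_mask(mi < params$immobility_threshold, t, rate,
                           params$immobility_min_dur,
                           params$immobility_min_sep)
  if (nrow(seg) == 0) return(new_bout_table())
  onset <- t[seg$start]
  offset <- t[seg$end] + 1 / rate
  mv <- mapply(function(s, e) mean(track$velocity[s:e]), seg$start, seg$end)
  new_bout_table(onset, offset, as.numeric(mv),
                 rep("immobility", nrow(seg)))
}

#' Summarize a bout table
#'
#' Per-session summary of a bout table over a known total recording (or
#' epoch) time: bout count, frequency per minute, mean duration and percent
#' of time spent in the state.
#'
#' @param bouts A bout table.
#' @param total_time Total time (s) the bouts were scored over.
#' @return One-row tibble: n, freq_per_min, mean_dur, pct_time.
#' @export
bout_summary <- function(bouts, total_time) {
  if (total_time <= 0) sf_param_error("total_time must be positive")
  n <- nrow(bouts)
  tibble::tibble(
    n = n,
    freq_per_min = n / (total_time / 60),
    mean_dur = if (n > 0) mean(bouts$duration) else NA_real_,
    pct_time = 100 * sum(bouts$duration) / total_time
  )
}

#' Classify behavioral state before a stimulation anchor
#'
#' Labels the 0.5 s immediately preceding a stimulation onset or offset:
#' ambulatory when every sample exceeds \code{ambulatory_threshold}
#' (2 cm/s), quiescent (which includes small movements) when every sample is
#' below \code{quiescent_threshold} (1.5 cm/s), otherwise unclassified. The
#' threshold gap guarantees the two labels cannot both apply.
#'
#' @param track A [behavior_track()].
#' @param anchor_time Anchor time (s).
#' @param anchor "stim_onset" or "stim_offset" (recorded in the output).
#' @param trial_index Trial number recorded in the output.
#' @param params [analysis_params()].
#' @return One-row tibble: trial_index, anchor, label. A window extending
#'   outside the recording yields label NA with a warning (the trial is
#'   skipped).
#' @export
classify_trial_state <- function(track, anchor_time,
                                 anchor = c("stim_onset", "stim_offset"),
                                 trial_index = 1L,
                                 params = analysis_params()) {
  stopifnot(inherits(track, "behavior_track"))
  anchor <- match.arg(anchor)
  w <- params$state_window
  idx <- window_idx(track$t, anchor_time - w, anchor_time)
  expected <- round(w * track$sample_rate)
  if (length(idx) < expected) {
    warning(sprintf(
      "trial %d (%s at %.3f s): state window extends outside the recording; skipped",
      trial_index, anchor, anchor_time), call. = FALSE)
    return(tibble::tibble(trial_index = trial_index, anchor = anchor,
                          label = NA_character_))
  }
  v <- track$velocity[idx]
  label <- if (all(v > params$ambulatory_threshold)) "ambulatory"
  else if (all(v < params$quiescent_threshold)) "quiescent"
  else "unclassified"
  tibble::tibble(trial_index = trial_index, anchor = anchor, label = label)
}

#' Classify state for every trial of a protocol
#'
#' Applies [classify_trial_state()] at the onset and offset of every trial in
#' a stimulation protocol.
#'
#' @param track A [behavior_track()].
#' @param protocol A [stim_protocol()].
#' @param params [analysis_params()].
#' @return Tibble with one row per (trial, anchor).
#' @export
classify_protocol_states <- function(track, protocol,
                                     params = analysis_params()) {
  stopifnot(inherits(protocol, "stim_protocol"))
  rows <- list()
  for (i in seq_along(protocol$trial_onsets)) {
    on <- protocol$trial_onsets[i]
    off <- on + protocol$trial_durations[i]
    rows[[length(rows) + 1]] <-
      classify_trial_state(track, on, "stim_onset", i, params)
    rows[[length(rows) + 1]] <-
      classify_trial_state(track, off, "stim_offset", i, params)
  }
  do.call(rbind, rows)
}

#' Stimulation-locked velocity change
#'
#' Mean velocity in the 1 s before and the 1 s after an anchor time
#' (half-open windows \code{[anchor - w, anchor)} and
#' \code{[anchor, anchor + w)}), the quantity used for stimulation-effect
#' t-tests on velocity.
#'
#' @param track A [behavior_track()].
#' @param anchor_time Anchor time (s).
#' @param params [analysis_params()]; \code{stim_velocity_window} sets the
#'   window length (default 1 s).
#' @return Named numeric: pre_mean, post_mean (cm/s).
#' @export
stim_velocity_change <- function(track, anchor_time,
                                 params = analysis_params()) {
  stopifnot(inherits(track, "behavior_track"))
  w <- params$stim_velocity_window
  pre <- window_idx(track$t, anchor_time - w, anchor_time)
  post <- window_idx(track$t, anchor_time, anchor_time + w)
  expected <- round(w * track$sample_rate)
  if (length(pre) < expected || length(post) < expected)
    sf_timing_error(sprintf(
      "velocity-change windows around %.3f s extend outside the recording",
      anchor_time))
  c(pre_mean = mean(track$velocity[pre]),
    post_mean = mean(track$velocity[post]))
}
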