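#' Analysis parameters
#'
#' Bundle of every numeric threshold used across the pipeline, with the
#' defaults used throughout the head-fixed treadmill, open-field and
#' stimulation analyses. All durations are seconds, velocities cm/s,
#' fluorescence thresholds percent dF/F. Any subset can be overridden by
#' name; the rest keep their defaults.
#'
#' @param move_threshold Velocity threshold (cm/s) separating movement from
#'   rest on the treadmill.
#' @param min_move_dur Minimum duration (s) of a valid treadmill movement bout.
#' @param min_move_mean_vel Minimum mean velocity (cm/s) of a valid movement
#'   bout.
#' @param min_rest_dur Minimum duration (s) for a sub-threshold run to count
#'   as a rest period.
#' @param ambulation_threshold Open-field ambulation velocity threshold (cm/s).
#' @param ambulation_min_dur Minimum merged ambulation bout duration (s).
#' @param ambulation_min_sep Maximum gap (s) across which ambulation runs are
#'   merged ("separated by more than this" keeps them distinct).
#' @param immobility_threshold Motion-index threshold (fraction of pixel
#'   change) below which a sample counts as immobile.
#' @param immobility_min_dur,immobility_min_sep Duration/merge rules (s) for
#'   immobility bouts.
#' @param state_window Length (s) of the pre-anchor window used to classify
#'   ambulatory vs quiescent trial state.
#' @param ambulatory_threshold Every sample above this (cm/s) in the state
#'   window makes a trial ambulatory.
#' @param quiescent_threshold Every sample below this (cm/s) makes it
#'   quiescent; must be below \code{ambulatory_threshold} so the labels cannot
#'   overlap.
#' @param stim_velocity_window Half-width (s) of the pre/post windows for
#'   stimulation-locked velocity change.
#' @param f0_window Sliding-window length (s) for the percentile baseline F0.
#' @param f0_percentile Percentile (0-100) used for F0.
#' @param butter_order,butter_corner Order and corner frequency (Hz) of the
#'   low-pass Butterworth applied to the reference dF/F0 (zero-phase, so the
#'   effective order is doubled).
#' @param qc_max_dff Inclusion requires max dF/F (percent) above this.
#' @param qc_max_corr Inclusion requires signal/reference Pearson r below this.
#' @param ransac_iter,ransac_min_inlier_frac RANSAC iteration budget and the
#'   minimum inlier fraction accepted as consensus before falling back to OLS.
#' @param peak_window Half-width (s) of the peak-timing search around an event.
#' @param slope_window Window (s, pair) before locomotion offset for the slope
#'   fit; default -0.5 to 0.
#' @param rise_baseline_window Window (s, pair) defining baseline activity
#'   before locomotion onset; default -1 to -0.5.
#' @param rise_window_len Sliding-window length (s) for rise detection (0.020).
#' @param rise_step Step (s) between sliding windows (0.002).
#' @param rise_alpha Per-step significance level of the right-tailed paired t.
#' @param rise_consecutive Number of consecutive significant steps defining a
#'   rise.
#' @param rise_stop Lag (s) at which the sliding search stops if no rise was
#'   found (windows may extend past the event).
#' @param rise_run_select When several runs of consecutive significant steps
#'   qualify: "longest" (default) takes the dominant sustained run as the
#'   rise, "first" the earliest qualifying run. See [rise_time()].
#' @param stim_baseline_window Pre-onset baseline length (s) subtracted from
#'   each stimulation trial.
#' @param stim_reduction_window Length (s) of the pre-offset window searched
#'   for the maximal reduction.
#' @param stim_post_window Post-offset window (s, pair) for the rebound mean;
#'   default 4 to 9.
#' @param stim_elevation_window Post-onset window (s, pair) for the initial
#'   elevation; default 0.5 to 1.
#' @param treadmill_rule_order Order in which the treadmill bout rules are
#'   applied: absorb short rests first (default) or filter movement runs first.
#'
#' @return An object of class \code{analysis_params} (a named list).
#' @export
#' @examples
#' p <- analysis_params(move_threshold = 0.3)
#' p$move_threshold
analysis_params <- function(move_threshold = 0.25,
                            min_move_dur = 0.5,
                            min_move_mean_vel = 0.5,
                            min_rest_dur = 0.8,
                            ambulation_threshold = 2,
                            ambulation_min_dur = 0.5,
                            ambulation_min_sep = 0.5,
                            immobility_threshold = 0.02,
                            immobility_min_dur = 0.5,
                            immobility_min_sep = 0.5,
                            state_window = 0.5,
                            ambulatory_threshold = 2,
                            quiescent_threshold = 1.5,
                            stim_velocity_window = 1.0,
                            f0_window = 5,
                            f0_percentile = 10,
                            butter_order = 2,
                            butter_corner = 3,
                            qc_max_dff = 1.5,
                            qc_max_corr = 0.6,
                            ransac_iter = 100,
                            ransac_min_inlier_frac = 0.25,
                            peak_window = 1,
                            slope_window = c(-0.5, 0),
                            rise_baseline_window = c(-1, -0.5),
                            rise_window_len = 0.020,
                            rise_step = 0.002,
                            rise_alpha = 0.05,
                            rise_consecutive = 5,
                            rise_stop = 0.5,
                            rise_run_select = c("longest", "first"),
                            stim_baseline_window = 5,
                            stim_reduction_window = 1,
                            stim_post_window = c(4, 9),
                            stim_elevation_window = c(0.5, 1),
                            treadmill_rule_order = c("absorb_first", "filter_first")) {
  treadmill_rule_order <- match.arg(treadmill_rule_order)
  rise_run_select <- match.arg(rise_run_select)
  p <- list(
    move_threshold = move_threshold, min_move_dur = min_move_dur,
    min_move_mean_vel = min_move_mean_vel, min_rest_dur = min_rest_dur,
    ambulation_threshold = ambulation_threshold,
    ambulation_min_dur = ambulation_min_dur,
    ambulation_min_sep = ambulation_min_sep,
    immobility_threshold = immobility_threshold,
    immobility_min_dur = immobility_min_dur,
    immobility_min_sep = immobility_min_sep,
    state_window = state_window,
    ambulatory_threshold = ambulatory_threshold,
    quiescent_threshold = quiescent_threshold,
    stim_velocity_window = stim_velocity_window,
    f0_window = f0_window, f0_percentile = f0_percentile,
    butter_order = butter_order, butter_corner = butter_corner,
    qc_max_dff = qc_max_dff, qc_max_corr = qc_max_corr,
    ransac_iter = ransac_iter,
    ransac_min_inlier_frac = ransac_min_inlier_frac,
    peak_window = peak_window, slope_window = slope_window,
    rise_baseline_window = rise_baseline_window,
    rise_window_len = rise_window_len, rise_step = rise_step,
    rise_alpha = rise_alpha, rise_consecutive = rise_consecutive,
    rise_stop = rise_stop, rise_run_select = rise_run_select,
    stim_baseline_window = stim_baseline_window,
    stim_reduction_window = stim_reduction_window,
    stim_post_window = stim_post_window,
    stim_elevation_window = stim_elevation_window,
    treadmill_rule_order = treadmill_rule_order
  )
  class(p) <- "analysis_params"
  validate_analysis_params(p)
  p
}

validate_analysis_params <- function(p) {
  durs <- c(p$min_move_dur, p$min_rest_dur, p$ambulation_min_dur,
            p$state_window, p$f0_window, p$rise_window_len, p$rise_step,
            p$stim_baseline_window, p$stim_reduction_window)
  if (any(!is.finite(durs)) || any(durs <= 0))
    sf_param_error("all duration parameters must be finite and > 0")
  if (p$quiescent_threshold >= p$ambulatory_threshold)
    sf_param_error("quiescent_threshold must be below ambulatory_threshold")
  if (p$f0_percentile <= 0 || p$f0_percentile >= 100)
    sf_param_error("f0_percentile must lie strictly between 0 and 100")
  invisible(p)
}

#' Load analysis parameters from a YAML config file
#'
#' Reads a flat YAML mapping of parameter names to values and applies it on
#' top of the defaults of [analysis_params()]. Unknown keys are an error, so
#' typos in a config file cannot silently fall back to defaults.
#'
#' @param path Path to a YAML file.
#' @return An \code{analysis_params} object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) sf_input_error(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) return(analysis_params())
  known <- names(formals(analysis_params))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0)
    sf_param_error(paste0("unknown parameter(s) in config: ",
                          paste(bad, collapse = ", ")))
  do.call(analysis_params, vals)
}

#' @export
print.analysis_params <- function(x, ...) {
  cat("<analysis_params>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
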