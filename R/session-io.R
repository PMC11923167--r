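#' Write a session bundle to disk
#'
#' Serializes a [session_bundle()] as a plain-text directory container:
#' \code{photometry.csv} (t, signal, reference), \code{behavior.csv}
#' (t, velocity[, motion_index]), \code{events.csv} (timestamp, label),
#' \code{stim.csv} (onset, duration, frequency, power) and \code{meta.yaml}
#' (sample rates, signal wavelength, subject id, schedule kind, free-form
#' metadata). Only the components present in the bundle are written. Floats
#' are written at full double precision, so a write/read round trip is
#' lossless.
#'
#' @param bundle A [session_bundle()].
#' @param path Directory to create/populate.
#' @return \code{path}, invisibly.
#' @export
write_session <- function(bundle, path) {
  stopifnot(inherits(bundle, "session_bundle"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(subject_id = bundle$subject_id, meta = bundle$meta)
  if (!is.null(bundle$photometry)) {
    p <- bundle$photometry
    readr::write_csv(tibble::tibble(t = p$t, signal = p$signal,
                                    reference = p$reference),
                     file.path(path, "photometry.csv"), progress = FALSE)
    readr::write_csv(p$events, file.path(path, "events.csv"), progress = FALSE)
    meta$photometry <- list(sample_rate = p$sample_rate,
                            signal_wavelength = p$signal_wavelength)
  }
  if (!is.null(bundle$behavior)) {
    b <- bundle$behavior
    df <- tibble::tibble(t = b$t, velocity = b$velocity)
    if (!is.null(b$motion_index)) df$motion_index <- b$motion_index
    readr::write_csv(df, file.path(path, "behavior.csv"), progress = FALSE)
    meta$behavior <- list(sample_rate = b$sample_rate,
                          calibration = b$calibration)
  }
  if (!is.null(bundle$stim)) {
    s <- bundle$stim
    readr::write_csv(
      tibble::tibble(onset = s$trial_onsets, duration = s$trial_durations,
                     frequency = s$pulse_frequency, power = s$power),
      file.path(path, "stim.csv"), progress = FALSE)
    meta$stim <- list(schedule_kind = s$schedule_kind,
                      pulse_width = s$pulse_width)
  }
  yaml::write_yaml(meta, file.path(path, "meta.yaml"))
  invisible(path)
}

read_csv_checked <- function(path, required, what) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    sf_schema_error(sprintf("%s (%s) is missing column(s): %s", what, path,
                            paste(missing, collapse = ", ")))
  df
}

infer_rate <- function(t, what) {
  if (length(t) < 2) sf_timing_error(paste0(what, ": need at least 2 samples"))
  dt <- diff(t)
  if (any(dt <= 0) || max(dt) - min(dt) > 1e-6 * stats::median(dt))
    sf_timing_error(paste0(what, ": time column is not a uniform grid"))
  1 / stats::median(dt)
}

#' Load a recording session
#'
#' Reads either the directory container written by [write_session()]
#' (\code{format = "dir"}) or a single long-format photometry CSV with
#' columns t, signal, reference (\code{format = "csv"}). Sample rates are
#' taken from \code{meta.yaml} when present, otherwise inferred from the time
#' column, which must be a uniform grid.
#'
#' @param path Directory (format "dir") or CSV file (format "csv").
#' @param format "dir" or "csv".
#' @return A [session_bundle()].
#' @export
load_session <- function(path, format = c("dir", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- read_csv_checked(path, c("t", "signal", "reference"),
                           "photometry CSV")
    rate <- infer_rate(df$t, "photometry CSV")
    return(session_bundle(
      photometry = photometry_session(df$t, df$signal, df$reference,
                                      sample_rate = rate)))
  }
  if (!dir.exists(path)) sf_input_error(paste0("no such session directory: ", path))
  meta_path <- file.path(path, "meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  phot <- beh <- stim <- NULL
  pp <- file.path(path, "photometry.csv")
  if (file.exists(pp)) {
    df <- read_csv_checked(pp, c("t", "signal", "reference"), "photometry table")
    rate <- meta$photometry$sample_rate %||% infer_rate(df$t, "photometry table")
    ev <- empty_events()
    ep <- file.path(path, "events.csv")
    if (file.exists(ep)) {
      ev <- read_csv_checked(ep, c("timestamp", "label"), "events table")
      ev$label <- as.character(ev$label)
    }
    phot <- photometry_session(
      df$t, df$signal, df$reference, sample_rate = rate,
      signal_wavelength = meta$photometry$signal_wavelength %||% 465,
      events = ev)
  }
  bp <- file.path(path, "behavior.csv")
  if (file.exists(bp)) {
    df <- read_csv_checked(bp, c("t", "velocity"), "behavior table")
    rate <- meta$behavior$sample_rate %||% infer_rate(df$t, "behavior table")
    beh <- behavior_track(df$t, df$velocity,
                          motion_index = df[["motion_index"]],
                          sample_rate = rate,
                          calibration = meta$behavior$calibration %||% 4)
  }
  sp <- file.path(path, "stim.csv")
  if (file.exists(sp)) {
    df <- read_csv_checked(sp, c("onset", "duration"), "stim table")
    stim <- stim_protocol(df$onset, df$duration,
                          pulse_frequency = df[["frequency"]][1] %||% 20,
                          power = df[["power"]][1] %||% 3,
                          pulse_width = meta$stim$pulse_width %||% 5,
                          schedule_kind = meta$stim$schedule_kind %||% "trial_varied")
  }
  if (is.null(phot) && is.null(beh) && is.null(stim))
    sf_schema_error(paste0("session directory has no recognised component: ", path))
  session_bundle(phot, beh, stim,
                 subject_id = meta$subject_id %||% "unknown",
                 meta = meta$meta %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resample a session onto one common timebase
#'
#' Linearly interpolates every stream of a bundle onto a single uniform grid
#' at \code{rate}, restricted to the overlapping time span of the components,
#' and re-zeroes the clock so the first aligned sample is t = 0. Event and
#' stimulation timestamps are shifted by the same clock offset but never
#' resampled. Applying the function twice gives the same result as once.
#'
#' @param bundle A [session_bundle()].
#' @param rate Target rate (Hz).
#' @return A [session_bundle()] on the common grid.
#' @export
align_common_timebase <- function(bundle, rate = 1000) {
  stopifnot(inherits(bundle, "session_bundle"))
  spans <- list()
  if (!is.null(bundle$photometry))
    spans$phot <- range(bundle$photometry$t)
  if (!is.null(bundle$behavior))
    spans$beh <- range(bundle$behavior$t)
  if (length(spans) == 0) return(bundle)
  lo <- max(vapply(spans, `[`, numeric(1), 1))
  hi <- min(vapply(spans, `[`, numeric(1), 2))
  if (hi - lo <= 1 / rate)
    sf_timing_error("components have no overlapping time span to align")
  n <- floor((hi - lo) * rate + 1e-9) + 1
  grid <- lo + (seq_len(n) - 1) / rate
  new_t <- grid - lo
  phot <- beh <- NULL
  if (!is.null(bundle$photometry)) {
    p <- bundle$photometry
    ev <- p$events
    if (nrow(ev) > 0) ev$timestamp <- ev$timestamp - lo
    ev <- ev[ev$timestamp >= new_t[1] - 1e-9 &
               ev$timestamp <= new_t[n] + 1e-9, , drop = FALSE]
    phot <- photometry_session(
      new_t,
      approx(p$t, p$signal, xout = grid, rule = 2)$y,
      approx(p$t, p$reference, xout = grid, rule = 2)$y,
      sample_rate = rate, signal_wavelength = p$signal_wavelength,
      events = ev)
  }
  if (!is.null(bundle$behavior)) {
    b <- bundle$behavior
    mi <- if (is.null(b$motion_index)) NULL else
      approx(b$t, b$motion_index, xout = grid, rule = 2)$y
    beh <- behavior_track(new_t,
                          approx(b$t, b$velocity, xout = grid, rule = 2)$y,
                          motion_index = mi, sample_rate = rate,
                          calibration = b$calibration)
  }
  stim <- bundle$stim
  if (!is.null(stim) && lo != 0) {
    stim <- stim_protocol(stim$trial_onsets - lo, stim$trial_durations,
                          pulse_frequency = stim$pulse_frequency,
                          pulse_width = stim$pulse_width, power = stim$power,
                          schedule_kind = stim$schedule_kind)
  }
  session_bundle(phot, beh, stim, subject_id = bundle$subject_id,
                 meta = bundle$meta)
}

#' Export a result table
#'
#' Writes any data-frame-like result (bout tables, metric tables, epoch
#' summaries) as CSV or TSV with a stable header and full-precision floats
#' (shortest round-trip representation, at least 15 significant digits), so a
#' re-import reproduces the values to better than 1e-9 relative.
#'
#' @param results A data frame; zero rows gives a header-only file.
#' @param path Output file path.
#' @param format "csv" or "tsv".
#' @return \code{path}, invisibly.
#' @export
export_table <- function(results, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (is.null(results)) sf_input_error("results must be a data frame, not NULL")
  df <- tibble::as_tibble(results)
  if (ncol(df) == 0) sf_input_error("results table has no columns")
  writer <- if (format == "csv") readr::write_csv else readr::write_tsv
  tryCatch(writer(df, path, progress = FALSE),
           error = function(e) sf_input_error(
             paste0("cannot write table to ", path, ": ", conditionMessage(e))))
  invisible(path)
}
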