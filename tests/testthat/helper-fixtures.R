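# In-code fixtures: velocity builders and random traces that avoid
# exact-threshold samples (samples exactly at threshold belong to neither
# class, and the generators must not graze them).

# velocity trace from (duration, level) segments at a given rate
square_velocity <- function(segments, rate = 100) {
  v <- unlist(lapply(segments, function(s) rep(s[2], round(s[1] * rate))))
  behavior_track(t = (seq_along(v) - 1) / rate, velocity = v,
                 sample_rate = rate)
}

# random piecewise-constant velocity avoiding the thresholds 0.25 and 2 cm/s
random_square_velocity <- function(rate = 100, max_dur = 60) {
  total <- stats::runif(1, 10, max_dur)
  segs <- list()
  t_acc <- 0
  levels <- c(0, 0.1, 0.4, 0.8, 1.4, 2.6, 4, 6)
  while (t_acc < total) {
    d <- stats::runif(1, 0.1, 3)
    segs[[length(segs) + 1]] <- c(d, sample(levels, 1))
    t_acc <- t_acc + d
  }
  square_velocity(segs, rate)
}

# motion-index trace from (duration, level) segments
square_motion_index <- function(segments, rate = 100, velocity_level = 0) {
  mi <- unlist(lapply(segments, function(s) rep(s[2], round(s[1] * rate))))
  behavior_track(t = (seq_along(mi) - 1) / rate,
                 velocity = rep(velocity_level, length(mi)),
                 motion_index = mi, sample_rate = rate)
}

expect_bouts_equal <- function(detected, oracle_mat, t, rate,
                               tol_samples = 1) {
  if (is.null(oracle_mat)) {
    expect_equal(nrow(detected), 0)
    return(invisible(NULL))
  }
  expect_equal(nrow(detected), nrow(oracle_mat))
  if (nrow(detected) == 0) return(invisible(NULL))
  on_err <- abs(detected$onset - t[oracle_mat[, 1]])
  off_err <- abs(detected$offset - (t[oracle_mat[, 2]] + 1 / rate))
  expect_lte(max(c(on_err, off_err)), tol_samples / rate + 1e-9)
}
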