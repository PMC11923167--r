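make_trial <- function(lags, dff, dur) {
  structure(list(trial_index = 1L, lags = lags, dff = dff,
                 stim_duration = dur, baseline = 0),
            class = "stim_trial_window")
}

test_that("trial extraction subtracts each trial's own baseline", {
  rate <- 100
  t <- (0:11999) / rate
  proto <- stim_protocol(c(20, 60, 100), 5, schedule_kind = "trial_10s")
  # constant dF/F: everything collapses to zero after baseline subtraction
  cst <- list(t = t, dff = rep(0.4, length(t)))
  trials <- extract_stim_trials(cst, proto)
  expect_length(trials, 3)
  for (tr in trials) {
    expect_lt(max(abs(tr$dff)), 1e-12)
    expect_equal(range(tr$lags), c(-5, 14))
  }

  # baseline-window mean is zero for arbitrary traces
  set.seed(101)
  rnd <- list(t = t, dff = rnorm(length(t)))
  for (tr in extract_stim_trials(rnd, proto)) {
    bl <- tr$dff[tr$lags >= -5 - 1e-9 & tr$lags < -1e-9]
    expect_lt(abs(mean(bl)), 1e-9)
  }

  # a trial too close to the session start is dropped with a message
  proto2 <- stim_protocol(c(2, 60), 5, schedule_kind = "trial_10s")
  expect_message(tr2 <- extract_stim_trials(rnd, proto2), "dropped 1")
  expect_length(tr2, 1)
})

test_that("the three stimulus metrics follow their window definitions", {
  rate <- 1000
  dur <- 5
  lags <- seq(-5 * rate, (dur + 9) * rate) / rate

  # elevation: boxcar of +0.5 over [0.3, 1.2) averages to 0.5 in [0.5, 1)
  box <- ifelse(lags >= 0.3 & lags < 1.2, 0.5, 0)
  expect_equal(initial_elevation(make_trial(lags, box, dur)), 0.5)
  expect_equal(initial_elevation(make_trial(lags, lags * 0, dur)), 0)

  # reduction: linear decline to -2 at offset; minimum sits at the last
  # in-window sample
  dec <- pmin(0, -2 * lags / dur)
  mr <- max_reduction(make_trial(lags, dec, dur))
  expect_equal(mr, -2 * (dur - 1 / rate) / dur, tolerance = 1e-12)

  # rebound: sampled-exponential mean matches the geometric closed form
  reb <- ifelse(lags > dur, exp(-(lags - dur) / 5), 0)
  expect_equal(post_stim_change(make_trial(lags, reb, dur)),
               geom_rebound_mean(1, 5, 4, 9, rate), tolerance = 1e-12)
  expect_equal(post_stim_change(make_trial(lags, lags * 0, dur)), 0)
  # residual suppression without rebound passes straight through
  expect_equal(post_stim_change(make_trial(lags, rep(-0.5, length(lags)),
                                           dur)), -0.5)

  # windows outside the trial extent raise, never truncate
  shortl <- seq(-5 * rate, (dur + 2) * rate) / rate
  expect_error(post_stim_change(make_trial(shortl, shortl * 0, dur)),
               class = "sf_timing_error")
})

test_that("adding a constant to the session leaves stim metrics unchanged", {
  rate <- 100
  t <- (0:11999) / rate
  proto <- stim_protocol(c(20, 60), 5, schedule_kind = "trial_10s")
  set.seed(7)
  dff <- 0.01 * sin(2 * pi * t / 13) + rnorm(length(t), 0, 0.002)
  s1 <- stim_response_summary(extract_stim_trials(list(t = t, dff = dff),
                                                  proto))
  s2 <- stim_response_summary(extract_stim_trials(
    list(t = t, dff = dff + 0.37), proto))
  expect_equal(s1$per_duration, s2$per_duration, tolerance = 1e-12)
})

test_that("phenotype-style presets order the metrics as expected", {
  rate <- 100
  proto <- stim_protocol(seq(20, 20 + 4 * 45, by = 45), 5,
                         schedule_kind = "trial_10s")
  run <- function(cfg) {
    sim <- simulate_stim_session(cfg, proto)
    ses <- sim$bundle$photometry
    nt <- reference_correct_stim(ses$signal, ses$reference, rate, seed = 1)
    nt$t <- ses$t
    stim_response_summary(extract_stim_trials(nt, proto))$per_duration
  }
  # terminator-like preset: no elevation, deep suppression, clear rebound
  k <- run(synth_config(duration = 260, rate = rate, elevation_amp = 0,
                        suppression_amp = 0.03, rebound_amp = 0.01,
                        noise_sd = 1e-4, seed = 31))
  # promoter-like preset: elevation, shallow suppression, no rebound
  c_ <- run(synth_config(duration = 260, rate = rate, elevation_amp = 0.01,
                         suppression_amp = 0.008, rebound_amp = 0,
                         noise_sd = 1e-4, seed = 32))
  expect_lt(k$max_reduction, c_$max_reduction)
  expect_lt(c_$max_reduction, 0)
  expect_gt(k$post_stim_change, 0.001)
  expect_lt(abs(c_$post_stim_change), 5e-4)
  expect_gt(c_$initial_elevation, 0.008)
  expect_lt(k$initial_elevation, 0.002)
})

test_that("mean-trace mode agrees with per-trial mode on noiseless data", {
  rate <- 100
  proto <- stim_protocol(c(20, 70, 120), 5, schedule_kind = "trial_10s")
  cfg <- synth_config(duration = 160, rate = rate, elevation_amp = 0.008,
                      suppression_amp = 0.02, rebound_amp = 0.01,
                      noise_sd = 0, seed = 33)
  sim <- simulate_stim_session(cfg, proto)
  nt <- reference_correct_stim(sim$bundle$photometry$signal,
                               sim$bundle$photometry$reference, rate,
                               seed = 1)
  nt$t <- sim$bundle$photometry$t
  trials <- extract_stim_trials(nt, proto)
  a <- stim_response_summary(trials, mean_trace = FALSE)$per_duration
  b <- stim_response_summary(trials, mean_trace = TRUE)$per_duration
  expect_equal(a$initial_elevation, b$initial_elevation, tolerance = 1e-6)
  expect_equal(a$post_stim_change, b$post_stim_change, tolerance = 1e-6)
  # the noiseless minimum is identical across trials, so the modes agree
  expect_equal(a$max_reduction, b$max_reduction, tolerance = 1e-4)
})

test_that("epoch summaries normalize velocity to the prior epoch", {
  rate <- 50
  ep <- 180
  proto <- stim_protocol(c(ep, 3 * ep), ep, schedule_kind = "epoch_3min")
  # constant 5 cm/s: all epoch means 5, all ratios 1
  n <- 5 * ep * rate
  t <- (seq_len(n) - 1) / rate
  cst <- behavior_track(t, rep(5, n), sample_rate = rate)
  s <- epoch_velocity_summary(cst, proto)
  expect_equal(s$mean_velocity, rep(5, 5))
  expect_equal(s$velocity_ratio, rep(1, 5))
  expect_equal(s$epoch, c("prior", "on1", "off1", "on2", "off2"))

  # velocity halved during light-on epochs
  v <- rep(5, n)
  on_idx <- (t >= ep & t < 2 * ep) | (t >= 3 * ep & t < 4 * ep)
  v[on_idx] <- 2.5
  sh <- epoch_velocity_summary(behavior_track(t, v, sample_rate = rate),
                               proto)
  expect_equal(sh$velocity_ratio[sh$epoch == "on1"], 0.5, tolerance = 1e-9)
  expect_equal(sh$velocity_ratio[sh$epoch == "off2"], 1, tolerance = 1e-9)

  # zero prior velocity: ratio undefined
  z <- behavior_track(t, c(rep(0, ep * rate), rep(5, n - ep * rate)),
                      sample_rate = rate)
  expect_error(epoch_velocity_summary(z, proto), class = "sf_numeric_error")

  # bouts straddling an epoch boundary count where they start
  vb <- rep(0, n)
  vb[t >= ep - 2 & t < ep + 2] <- 6        # bout crossing prior -> on1
  bb <- epoch_velocity_summary(behavior_track(t, vb, sample_rate = rate),
                               proto)
  expect_equal(bb$ambulation_freq[bb$epoch == "prior"] * 3, 1)
  expect_equal(bb$ambulation_freq[bb$epoch == "on1"], 0)
  # and the clipped duration stays inside the epoch
  expect_equal(bb$ambulation_dur[bb$epoch == "prior"], 2, tolerance = 0.05)
})
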