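test_that("sliding percentile baseline matches the brute-force oracle", {
  set.seed(31)
  rate <- 100
  x <- 5 + cumsum(rnorm(1000, 0, 0.05)) + rnorm(1000, 0, 0.2)
  f0 <- sliding_percentile_baseline(x, rate, window = 5, percentile = 10)
  expect_equal(f0, oracle_sliding_percentile(x, rate), tolerance = 1e-13)

  # constant trace: F0 is the constant
  expect_equal(sliding_percentile_baseline(rep(3, 800), rate), rep(3, 800))

  # increasing ramp: interior F0 lies strictly below the trace
  r <- seq(1, 2, length.out = 1000)
  f0r <- sliding_percentile_baseline(r, rate)
  interior <- 300:700
  expect_true(all(f0r[interior] < r[interior]))
  expect_equal(f0r, oracle_sliding_percentile(r, rate), tolerance = 1e-13)

  # a brief positive spike (well under 10% of the window) leaves F0 alone:
  # on a smooth ramp the spiked samples rank well above the bottom decile of
  # every window centered near them
  xs <- r
  xs[500:520] <- xs[500:520] + 50
  f0s <- sliding_percentile_baseline(xs, rate)
  expect_equal(f0s[480:540], f0r[480:540], tolerance = 1e-12)

  expect_error(sliding_percentile_baseline(x, rate, window = -1),
               class = "sf_param_error")
  expect_error(sliding_percentile_baseline(x[1:100], rate, window = 5),
               class = "sf_param_error")
})

test_that("dF/F0 pre-normalization follows its definition", {
  f0 <- seq(2, 1, length.out = 100)
  expect_equal(prenormalize_dff(f0, f0), rep(0, 100))
  expect_equal(prenormalize_dff(1.1 * f0, f0), rep(0.1, 100),
               tolerance = 1e-12)
  bad <- f0; bad[42] <- -1
  err <- tryCatch(prenormalize_dff(f0, bad), error = identity)
  expect_s3_class(err, "sf_numeric_error")
  expect_match(conditionMessage(err), "42")

  # slow pure bleach: dF/F0 stays under 1% away from the edges
  rate <- 100
  t <- (0:9999) / rate
  bleach <- exp(-t / 500)               # tau = 100 x window
  dff <- prenormalize_dff(bleach, sliding_percentile_baseline(bleach, rate))
  interior <- 500:9500
  expect_lt(max(abs(dff[interior])), 0.01)
})

test_that("session z-score is exact and affine-invariant", {
  set.seed(7)
  x <- rnorm(1e5, 3, 2)
  z <- zscore_session(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_equal(zscore_session(5 * x - 2), z, tolerance = 1e-10)
  # two-pass brute force
  expect_equal(z, (x - sum(x) / length(x)) /
                 sqrt(sum((x - mean(x))^2) / (length(x) - 1)),
               tolerance = 1e-10)
  expect_error(zscore_session(rep(1, 10)), class = "sf_numeric_error")
})

test_that("QC applies the inclusion rule exactly", {
  p <- analysis_params()
  set.seed(8)
  base <- rnorm(2000, 0, 0.001)
  ref <- rnorm(2000, 0, 0.001)
  hi <- base; hi[100] <- 0.03           # max dF/F = 3%
  lo <- base; lo[100] <- 0.01           # max dF/F = 1%
  q1 <- qc_session(hi, ref, p)          # strong signal, low corr -> in
  expect_true(q1$included)
  q2 <- qc_session(lo, ref, p)          # weak signal -> out
  expect_false(q2$included)
  expect_match(q2$reason, "low signal")
  corr_ref <- hi * 2 + rnorm(2000, 0, 0.001)   # r > 0.6 -> out
  q3 <- qc_session(hi, corr_ref, p)
  expect_false(q3$included)
  expect_match(q3$reason, "motion")
  q4 <- qc_session(lo, corr_ref, p)     # both violated -> out
  expect_false(q4$included)
  # zero variance -> excluded with reason, not an error
  q5 <- qc_session(rep(0.02, 100), rnorm(100), p)
  expect_false(q5$included)
  expect_match(q5$reason, "zero-variance")
})

test_that("RANSAC resists outliers and falls back without consensus", {
  set.seed(41)
  x <- rnorm(500)
  y <- 2 * x + 1 + rnorm(500, 0, 0.01)
  y[1:60] <- y[1:60] + 8            # 12% gross outliers
  fit <- ransac_lm(x, y, seed = 1)
  expect_false(fit$fallback_ols)
  expect_equal(fit$slope, 2, tolerance = 0.01)
  expect_equal(fit$intercept, 1, tolerance = 0.01)
  expect_lt(mean(fit$inliers[1:60]), 0.1)

  # exactly affine data (zero MAD) still fits
  fe <- ransac_lm(x, 3 * x - 2, seed = 2)
  expect_equal(fe$slope, 3, tolerance = 1e-9)
  expect_equal(fe$intercept, -2, tolerance = 1e-9)

  # degenerate predictor (no valid candidate pair) triggers the OLS fallback
  expect_warning(fb <- ransac_lm(rep(1, 50), rnorm(50), seed = 3),
                 "consensus")
  expect_true(fb$fallback_ols)
})

test_that("behavior-mode referencing removes what it should", {
  rate <- 100
  p <- analysis_params()
  # reference identical to signal: corrected trace collapses to ~0
  set.seed(51)
  s <- 0.01 * sin(2 * pi * 0.5 * (0:1999) / rate)
  cb <- reference_correct_behavior(s, s, rate, p, seed = 1)
  # zero-phase filtering has edge transients; away from them the corrected
  # trace collapses to numerical zero
  expect_lt(max(abs(cb$dff[200:1800])), 1e-6)

  # white-noise reference, uncorrelated with the signal: fitted slope ~ 0
  # (low-pass filtering leaves ~17-sample correlation in the regressor, so
  # the slope SE scales with the effective, not nominal, sample count)
  slopes <- vapply(1:50, function(i) {
    set.seed(100 + i)
    sig <- 0.005 * sin(2 * pi * 0.3 * (0:19999) / rate) +
      rnorm(20000, 0, 0.002)
    ref <- rnorm(20000, 0, 0.1)
    reference_correct_behavior(sig, ref, rate, p, seed = i)$fit$slope
  }, numeric(1))
  expect_lt(max(abs(slopes)), 0.05)
})

test_that("stim-mode referencing recovers fractional responses", {
  rate <- 100
  t <- (0:5999) / rate
  f_true <- 2 * exp(-t / 300)
  r_t <- 0.002 * sin(2 * pi * t / 6)    # small known fractional response
  sig <- f_true * (1 + r_t)
  nt <- reference_correct_stim(sig, f_true, rate, seed = 4)
  expect_lt(max(abs(nt$dff - r_t)), 1e-3)
  expect_equal(nt$method, "stim_mode")

  # exact doubling: F equals the signal, dF/F is identically zero
  nt2 <- reference_correct_stim(2 * f_true, f_true, rate, seed = 5)
  expect_lt(max(abs(nt2$dff)), 1e-9)

  # negative referenced F is a numeric-domain error
  expect_error(reference_correct_stim(-f_true, f_true, rate, seed = 6),
               class = "sf_numeric_error")
})

test_that("full behavior-mode pipeline returns coherent sessions", {
  cfg <- synth_config(duration = 120, rate = 100, seed = 17)
  sim <- simulate_treadmill_session(cfg)
  nt <- normalize_behavior_session(sim$bundle$photometry, seed = 17)
  expect_s3_class(nt, "normalized_trace")
  expect_length(nt$dff, length(sim$bundle$photometry$t))
  expect_lt(abs(mean(nt$zscore)), 1e-9)
  expect_lt(abs(sd(nt$zscore) - 1), 1e-9)
  expect_true(nt$qc$included)
})
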