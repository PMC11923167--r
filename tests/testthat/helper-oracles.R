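# Independent brute-force oracles. These deliberately avoid the package's
# run-length machinery: everything is computed by per-sample scans and
# stats:: primitives so detector bugs cannot hide in shared code.

# per-sample sliding percentile (type-7), centered truncated window
oracle_sliding_percentile <- function(x, rate, window = 5, percentile = 10) {
  w <- round(window * rate)
  h <- floor(w / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    stats::quantile(x[max(1, i - h):min(n, i + h)], percentile / 100,
                    type = 7, names = FALSE)
  }, numeric(1))
}

# exhaustive scan for treadmill movement bouts (absorb-first rule order)
oracle_treadmill_scan <- function(v, rate, move_thr = 0.25, min_move = 0.5,
                                  min_mean = 0.5, min_rest = 0.8) {
  n <- length(v)
  lab <- integer(n)                      # 1 move, 0 rest, -1 at-threshold
  for (i in seq_len(n)) lab[i] <- if (v[i] > move_thr) 1L else
    if (v[i] < move_thr) 0L else -1L
  segs <- list()                         # collect maximal runs by scanning
  s <- 1L
  for (i in seq_len(n)) {
    if (i == n || lab[i + 1] != lab[i]) {
      segs[[length(segs) + 1]] <- c(lab[s], s, i)
      s <- i + 1L
    }
  }
  m <- do.call(rbind, segs)
  # absorb short rests adjacent to movement
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(m))) {
      if (m[k, 1] == 0L && (m[k, 3] - m[k, 2] + 1) / rate <= min_rest) {
        prev_m <- k > 1 && m[k - 1, 1] == 1L
        next_m <- k < nrow(m) && m[k + 1, 1] == 1L
        if (prev_m || next_m) {
          m[k, 1] <- 1L
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  # re-merge adjacent equal labels
  merged <- list()
  for (k in seq_len(nrow(m))) {
    if (length(merged) > 0 && merged[[length(merged)]][1] == m[k, 1]) {
      merged[[length(merged)]][3] <- m[k, 3]
    } else merged[[length(merged) + 1]] <- m[k, ]
  }
  m <- do.call(rbind, merged)
  out <- NULL
  for (k in seq_len(nrow(m))) {
    if (m[k, 1] != 1L) next
    dur <- (m[k, 3] - m[k, 2] + 1) / rate
    mv <- mean(v[m[k, 2]:m[k, 3]])
    if (dur < min_move || mv < min_mean) next
    ok_pre <- k > 1 && m[k - 1, 1] == 0L &&
      (m[k - 1, 3] - m[k - 1, 2] + 1) / rate > min_rest
    ok_post <- k < nrow(m) && m[k + 1, 1] == 0L &&
      (m[k + 1, 3] - m[k + 1, 2] + 1) / rate > min_rest
    if (ok_pre && ok_post)
      out <- rbind(out, c(start = m[k, 2], end = m[k, 3], mean_vel = mv))
  }
  out
}

# exhaustive scan for merge-then-filter bouts (ambulation / immobility)
oracle_merge_scan <- function(x, rate, thr, min_dur, min_sep,
                              below = FALSE) {
  inb <- if (below) x < thr else x > thr
  n <- length(x)
  runs <- NULL
  s <- NA_integer_
  for (i in seq_len(n)) {
    if (inb[i] && is.na(s)) s <- i
    if (!is.na(s) && (i == n || !inb[i + 1])) {
      if (inb[i]) {
        runs <- rbind(runs, c(s, i))
        s <- NA_integer_
      } else s <- NA_integer_
    }
    if (!inb[i]) s <- NA_integer_
  }
  if (is.null(runs)) return(NULL)
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (k in 2:nrow(runs)) {
      gap <- (runs[k, 1] - merged[nrow(merged), 2] - 1) / rate
      if (gap <= min_sep) merged[nrow(merged), 2] <- runs[k, 2]
      else merged <- rbind(merged, runs[k, ])
    }
  }
  keep <- (merged[, 2] - merged[, 1] + 1) / rate > min_dur
  if (!any(keep)) return(NULL)
  merged[keep, , drop = FALSE]
}

# brute-force peri-event mean trace
oracle_aligned_mean <- function(z, t, events, window, rate) {
  k1 <- round(window[1] * rate); k2 <- round(window[2] * rate)
  segs <- list()
  for (e in events) {
    ie <- round((e - t[1]) * rate) + 1
    if (ie + k1 >= 1 && ie + k2 <= length(z))
      segs[[length(segs) + 1]] <- z[(ie + k1):(ie + k2)]
  }
  Reduce(`+`, segs) / length(segs)
}

# rise-time re-implementation with stats::t.test at every step
oracle_rise_time <- function(aligned, params = analysis_params()) {
  lags <- aligned$lags; mat <- aligned$mat
  rate <- 1 / (lags[2] - lags[1])
  bl <- rowMeans(mat[, lags >= -1 - 1e-9 & lags < -0.5 - 1e-9, drop = FALSE])
  len_s <- max(2L, round(params$rise_window_len * rate))
  step_s <- max(1L, round(params$rise_step * rate))
  i0 <- round((-0.5 - lags[1]) * rate) + 1
  starts <- seq(i0, length(lags) - len_s + 1, by = step_s)
  starts <- starts[lags[starts] + params$rise_window_len <=
                     params$rise_stop + 1e-9]
  pv <- vapply(starts, function(s) {
    wm <- rowMeans(mat[, s:(s + len_s - 1), drop = FALSE])
    if (stats::sd(wm - bl) == 0) return(1)
    stats::t.test(wm, bl, paired = TRUE, alternative = "greater")$p.value
  }, numeric(1))
  sig <- pv < params$rise_alpha
  r <- rle(sig); ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= params$rise_consecutive)
  if (length(hit) == 0) return(NA_real_)
  pick <- if (params$rise_run_select == "longest")
    hit[which.max(r$lengths[hit])] else hit[1]
  first <- ends[pick] - r$lengths[pick] + 1
  lags[starts[first]] + params$rise_window_len / 2
}

# exact mean of amp * exp(-(t - off)/tau) over the sampled window
# [off + a, off + b): a geometric series, so exact to machine precision
geom_rebound_mean <- function(amp, tau, a, b, rate) {
  dt <- 1 / rate
  lags <- seq(a, b - dt / 2, by = dt)
  q <- exp(-dt / tau)
  n <- length(lags)
  amp * exp(-a / tau) * (1 - q^n) / (n * (1 - q))
}
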