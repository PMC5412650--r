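# Shared fixtures and independent oracles, built in code at test time.

# Noise-free train of Gaussian wavelets at the given centre times.
wavelet_train_ts <- function(times, fs = 1000, duration = NULL, sigma = 0.025,
                             amp = 1, noise = 0, label = "train") {
  duration <- duration %||% (max(times) + 1)
  tt <- seq(0, duration - 1 / fs, by = 1 / fs)
  x <- numeric(length(tt))
  for (tc in times) x <- x + amp * exp(-(tt - tc)^2 / (2 * sigma^2))
  if (noise > 0) x <- x + rnorm(length(x), sd = noise)
  timeseries(x, fs, label = label)
}

# Brute-force oracle for guided peak search: literal argmax over every sample
# in [ref + lag_min, ref + lag_max], scanning linearly.
oracle_guided_argmax <- function(ts, ref_times, lag_min, lag_max) {
  tt <- ts_time(ts)
  vapply(ref_times, function(rt) {
    sel <- which(tt >= rt + lag_min - 1e-9 & tt <= rt + lag_max + 1e-9)
    if (!length(sel)) return(NA_real_)
    tt[sel[which.max(ts$samples[sel])]]
  }, numeric(1))
}

# Naive O(n * m) matching oracle for compute_ptt: for every proximal beat,
# scan all distal events, keep those in the window, take the earliest.
oracle_ptt_match <- function(proximal, distal, lag_window) {
  out <- data.frame(beat_time = numeric(0), ptt = numeric(0))
  for (p in proximal) {
    best <- NA_real_
    for (d in distal) {
      lag <- d - p
      if (lag > lag_window[1] - 1e-12 && lag < lag_window[2] + 1e-12) {
        if (is.na(best) || d < best) best <- d
      }
    }
    if (!is.na(best)) out <- rbind(out, data.frame(beat_time = p, ptt = best - p))
  }
  out
}

# Fraction of true event times recovered within tol by a detected series.
recovery_rate <- function(detected, truth, tol = 0.02) {
  if (!length(truth)) return(NA_real_)
  hits <- vapply(truth, function(t) any(abs(detected - t) <= tol), logical(1))
  mean(hits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
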