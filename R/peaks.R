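#' Reference beat detection on an accelerometer or MEG channel
#'
#' Finds the heartbeat peaks on the channel with the clearest pulse waveform
#' (the "reference" channel): local maxima above an adaptive threshold
#' (a fraction of the rolling 95th percentile), separated by at least a
#' refractory interval. Candidates are accepted in decreasing amplitude order
#' (ties: earliest sample), so a large peak always wins over a smaller one
#' closer than `min_interval`. A flat signal yields an empty event series,
#' not an error.
#'
#' @param ts A [timeseries()]; duration must exceed `2 * min_interval`.
#' @param min_interval Refractory period in s (> 0); default 0.4 s.
#' @param polarity `"positive"`, `"negative"` or `"absolute"`: which extreme
#'   counts as a peak.
#' @param smoothing_bandwidth Optional low-pass pre-filter cutoff (Hz);
#'   `NULL` detects on the raw samples.
#' @param threshold_fraction Fraction of the rolling 95th percentile used as
#'   the detection threshold (default 0.5).
#' @param threshold_window Window for the rolling percentile in s (default 10).
#' @return An [event_series()] of beat times (sample resolution).
#' @details Detection is invariant to positive affine rescaling of the
#'   signal: the threshold is computed on the median-centred signal, so
#'   `a * x + b` (a > 0) yields identical event times.
#' @export
detect_reference_peaks <- function(ts, min_interval = 0.4,
                                   polarity = c("positive", "negative", "absolute"),
                                   smoothing_bandwidth = NULL,
                                   threshold_fraction = 0.5,
                                   threshold_window = 10) {
  stopifnot(inherits(ts, "hp_ts"))
  polarity <- match.arg(polarity)
  if (min_interval <= 0) abort("`min_interval` must be > 0.", class = "hp_param_error")
  if (ts_duration(ts) <= 2 * min_interval)
    abort("Signal shorter than 2 * min_interval.", class = "hp_param_error")

  x <- ts$samples
  if (!is.null(smoothing_bandwidth)) {
    if (smoothing_bandwidth >= ts$fs / 2)
      abort("`smoothing_bandwidth` must be below Nyquist.", class = "hp_param_error")
    bf <- signal::butter(4, smoothing_bandwidth / (ts$fs / 2), type = "low")
    x <- signal::filtfilt(bf, x)
  }
  x <- switch(polarity, positive = x, negative = -x, absolute = abs(x))
  x <- x - median(x)  # affine invariance of the adaptive threshold

  n <- length(x)
  # adaptive threshold: 95th percentile per threshold_window block (step fn)
  block <- max(1L, round(threshold_window * ts$fs))
  starts <- seq(1L, n, by = block)
  thr <- numeric(n)
  for (s in starts) {
    e <- min(s + block - 1L, n)
    thr[s:e] <- threshold_fraction * quantile(x[s:e], 0.95, names = FALSE)
  }

  cand <- which(x > pmax(thr, 0) &
                  x > c(-Inf, x[-n]) &
                  x >= c(x[-1], -Inf))
  if (!length(cand)) return(event_series(numeric(0), label = "beats"))

  # greedy: largest first, earliest on ties, enforce the refractory interval
  ord <- cand[order(-x[cand], cand)]
  min_gap <- min_interval * ts$fs
  keep <- logical(n)
  taken <- integer(0)
  for (i in ord) {
    if (!length(taken) || all(abs(taken - i) >= min_gap)) {
      keep[i] <- TRUE
      taken <- c(taken, i)
    }
  }
  idx <- which(keep)
  event_series(ts$start_time + (idx - 1) / ts$fs, label = "beats")
}

#' Reference-guided peak detection
#'
#' For each reference event, searches a synchronously measured signal for the
#' maximum value inside the lag window `[ref + lag_min, ref + lag_max]`
#' (clipped to the signal span) and returns the per-beat argmax — the
#' standard "maximum of each time interval" pairing of a distal pulse with
#' its proximal beat. At equal maxima the earliest sample wins, so the result
#' is exactly reproducible by a brute-force windowed argmax.
#'
#' @param ts The signal to search (an [timeseries()]).
#' @param reference An [event_series()] of proximal beat times (non-empty).
#' @param lag_min,lag_max Search window relative to each reference event, in
#'   s; defaults 0.02-0.4 s cover physiological chest-to-neck transit times.
#' @param polarity As in [detect_reference_peaks()].
#' @param smoothing_bandwidth Optional zero-phase low-pass cutoff (Hz)
#'   applied before the search; a symmetric pulse keeps its peak position,
#'   so smoothing only suppresses noise-driven argmax jitter. `NULL` (the
#'   default) searches the raw samples, where the result equals the
#'   brute-force windowed argmax exactly.
#' @return A tibble with one row per reference event: `ref_time`, `time`
#'   (the detected peak, `NA` when the window lies entirely outside the
#'   signal span — the beat is marked missing, never fabricated).
#' @export
detect_peaks_guided <- function(ts, reference, lag_min = 0.02, lag_max = 0.4,
                                polarity = c("positive", "negative", "absolute"),
                                smoothing_bandwidth = NULL) {
  stopifnot(inherits(ts, "hp_ts"), inherits(reference, "hp_events"))
  polarity <- match.arg(polarity)
  if (!length(reference$times)) abort("Reference events must be non-empty.", class = "hp_param_error")
  if (lag_max <= lag_min) abort("`lag_max` must exceed `lag_min`.", class = "hp_param_error")

  x <- ts$samples
  if (!is.null(smoothing_bandwidth)) {
    if (smoothing_bandwidth >= ts$fs / 2)
      abort("`smoothing_bandwidth` must be below Nyquist.", class = "hp_param_error")
    bf <- signal::butter(4, smoothing_bandwidth / (ts$fs / 2), type = "low")
    x <- signal::filtfilt(bf, x)
  }
  x <- switch(polarity, positive = x, negative = -x, absolute = abs(x))
  n <- length(x)
  t0 <- ts$start_time
  fs <- ts$fs

  peak_time <- vapply(reference$times, function(rt) {
    i0 <- ceiling((rt + lag_min - t0) * fs - 1e-9) + 1
    i1 <- floor((rt + lag_max - t0) * fs + 1e-9) + 1
    i0 <- max(i0, 1L)
    i1 <- min(i1, n)
    if (i0 > i1) return(NA_real_)
    w <- x[i0:i1]
    t0 + (i0 + which.max(w) - 2) / fs   # which.max takes the earliest tie
  }, numeric(1))

  tibble(ref_time = reference$times, time = peak_time)
}

#' Automated beat-series quality control
#'
#' Replaces the manual visual check of detected beats with a reproducible
#' rule: beats creating physiologically impossible inter-beat intervals
#' (outside `interval_range`, default 0.3-2.0 s) are repaired or flagged.
#' Short intervals drop whichever of the two offending events yields a merged
#' interval closer to the median beat interval; intervals exceeding
#' `gap_factor` times the median (or the absolute upper bound, whichever
#' bites first) are flagged as missed-beat gaps — never filled.
#'
#' @param events An [event_series()] of beat times.
#' @param interval_range Plausible inter-beat interval range in s.
#' @param gap_factor Multiple of the median interval above which an interval
#'   counts as a missed-beat gap (default 1.75: one dropped beat doubles the
#'   interval).
#' @return List with `events` (cleaned [event_series()]) and `report`, a
#'   tibble with `n_in`, `n_removed`, `n_gaps`, and `removed_times`.
#' @export
qc_beat_series <- function(events, interval_range = c(0.3, 2.0), gap_factor = 1.75) {
  stopifnot(inherits(events, "hp_events"))
  times <- events$times
  removed <- numeric(0)
  if (length(times) >= 3) {
    med <- median(diff(times))
    repeat {
      dts <- diff(times)
      bad <- which(dts < interval_range[1])
      if (!length(bad)) break
      i <- bad[1]  # short interval between times[i] and times[i + 1]
      merged_if_drop_right <- if (i + 2 <= length(times)) times[i + 2] - times[i] else Inf
      merged_if_drop_left <- if (i - 1 >= 1) times[i + 1] - times[i - 1] else Inf
      drop <- if (abs(merged_if_drop_right - med) <= abs(merged_if_drop_left - med))
        i + 1 else i
      removed <- c(removed, times[drop])
      times <- times[-drop]
    }
  }
  gap_limit <- if (length(times) >= 3)
    min(interval_range[2], gap_factor * median(diff(times))) else interval_range[2]
  n_gaps <- if (length(times) > 1) sum(diff(times) > gap_limit) else 0L
  list(
    events = event_series(times, label = events$label),
    report = tibble(n_in = length(events$times),
                    n_removed = length(removed),
                    n_gaps = as.integer(n_gaps),
                    removed_times = list(removed))
  )
}
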