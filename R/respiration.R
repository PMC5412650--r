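#' Respiration waveform from an accelerometer channel
#'
#' The chest (or neck) accelerometer sees breathing as a slow chest-wall
#' movement underneath the cardiac pulses; a zero-phase 0.5 Hz low-pass
#' isolates it. Same rate and length as the input.
#'
#' @param acm An accelerometer [timeseries()]; rate must exceed `2 * cutoff`.
#' @param cutoff Low-pass cutoff in Hz (default 0.5).
#' @return A [timeseries()] holding the respiration waveform.
#' @export
extract_respiration <- function(acm, cutoff = 0.5) {
  stopifnot(inherits(acm, "hp_ts"))
  if (cutoff >= acm$fs / 2)
    abort("`cutoff` must be below the Nyquist frequency.", class = "hp_param_error")
  out <- bandpass(acm, 0, cutoff)
  out$label <- paste0(acm$label, "_resp")
  out
}

#' Detect breath-hold intervals from a respiration waveform
#'
#' Breath holds appear as stretches where the respiration waveform goes
#' quiet. The rolling standard deviation (5 s windows) forms an envelope;
#' maximal runs where the envelope stays below `quiet_threshold` times the
#' recording-median envelope, lasting at least `min_duration`, are reported.
#' Because the centred rolling window smears the envelope by half its width,
#' each run is then expanded outward to where the envelope crosses half the
#' median (a hysteresis boundary), which places onsets and offsets at the
#' actual transition rather than half a window inside it. When task markers
#' exist they should be preferred — this detector is a convenience for
#' marker-free recordings.
#'
#' @param resp A respiration [timeseries()] (e.g. from
#'   [extract_respiration()]).
#' @param min_duration Minimum hold length in s (default 10).
#' @param quiet_threshold Envelope threshold as a fraction of the median
#'   envelope (default 0.25).
#' @param envelope_window Rolling-SD window in s (default 5).
#' @return A tibble with columns `onset`, `offset` (s) and `source`
#'   (`"detected"`); zero rows when nothing qualifies. Intervals never
#'   overlap and are each at least `min_duration` long.
#' @export
detect_breath_holds <- function(resp, min_duration = 10, quiet_threshold = 0.25,
                                envelope_window = 5) {
  stopifnot(inherits(resp, "hp_ts"))
  x <- resp$samples
  n <- length(x)
  w <- max(2L, round(envelope_window * resp$fs))
  # rolling SD via cumulative sums (O(n))
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  lo <- pmax(1L, seq_len(n) - w %/% 2L)
  hi <- pmin(n, seq_len(n) + w %/% 2L)
  cnt <- hi - lo + 1
  mu <- (cs[hi + 1] - cs[lo]) / cnt
  env <- sqrt(pmax(0, (cs2[hi + 1] - cs2[lo]) / cnt - mu^2))

  med <- median(env)
  thr <- quiet_threshold * med
  quiet <- env <= thr
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths / resp$fs >= min_duration)
  starts <- starts[keep]
  ends <- ends[keep]

  # hysteresis: expand each core run to the half-median envelope crossing
  hi <- 0.5 * med
  for (k in seq_along(starts)) {
    while (starts[k] > 1 && env[starts[k] - 1] <= hi) starts[k] <- starts[k] - 1L
    while (ends[k] < n && env[ends[k] + 1] <= hi) ends[k] <- ends[k] + 1L
  }
  # expansion can make neighbouring runs touch; merge to keep them disjoint
  if (length(starts) > 1) {
    keep2 <- c(TRUE, starts[-1] > ends[-length(ends)])
    merged_ends <- ends
    for (k in rev(which(!keep2))) merged_ends[k - 1] <- max(merged_ends[k - 1], merged_ends[k])
    starts <- starts[keep2]
    ends <- merged_ends[keep2]
  }
  tibble(
    onset = resp$start_time + (starts - 1) / resp$fs,
    offset = resp$start_time + (ends - 1) / resp$fs,
    source = "detected"
  )
}
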