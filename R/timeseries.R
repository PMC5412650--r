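#' Uniformly sampled single-channel time series
#'
#' `timeseries()` is the basic container for one uniformly sampled sensor
#' channel (accelerometer, MEG channel, NIRS intensity, respiration belt).
#' Time is always in seconds with `t = 0` at recording start unless
#' `start_time` says otherwise; events elsewhere in the package are expressed
#' in this recording time, never in sample indices.
#'
#' @param samples Numeric vector of samples, all finite, length >= 1.
#' @param fs Sampling rate in Hz (> 0).
#' @param start_time Time of the first sample in seconds (default 0).
#' @param label Channel label.
#' @param units Physical units of the samples (free text, e.g. "m/s^2").
#' @return An object of class `hp_ts`.
#' @examples
#' ts <- timeseries(sin(2 * pi * 1 * seq(0, 2, by = 1e-3)), fs = 1000,
#'                  label = "chest", units = "a.u.")
#' ts_duration(ts)
#' @export
timeseries <- function(samples, fs, start_time = 0, label = "", units = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 1) abort("`samples` must have length >= 1.", class = "hp_invariant_error")
  if (!all(is.finite(samples))) abort("All samples must be finite.", class = "hp_invariant_error")
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    abort("`fs` must be a single positive number (Hz).", class = "hp_invariant_error")
  structure(
    list(samples = samples, fs = as.numeric(fs), start_time = as.numeric(start_time),
         label = as.character(label), units = as.character(units)),
    class = "hp_ts"
  )
}

#' @export
print.hp_ts <- function(x, ...) {
  cat(sprintf("<hp_ts> %s: %d samples @ %g Hz, %.3f-%.3f s%s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$samples), x$fs, x$start_time,
              x$start_time + (length(x$samples) - 1) / x$fs,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  invisible(x)
}

#' Sample times of a time series
#' @param ts An `hp_ts`.
#' @return Numeric vector of sample times in seconds.
#' @export
ts_time <- function(ts) {
  stopifnot(inherits(ts, "hp_ts"))
  ts$start_time + (seq_along(ts$samples) - 1) / ts$fs
}

#' Duration of a time series in seconds
#' @param ts An `hp_ts`.
#' @return Duration (n / fs) in seconds.
#' @export
ts_duration <- function(ts) {
  stopifnot(inherits(ts, "hp_ts"))
  length(ts$samples) / ts$fs
}

#' @export
as_tibble.hp_ts <- function(x, ...) {
  tibble(time = ts_time(x), value = x$samples)
}

#' @export
autoplot.hp_ts <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)",
                  y = if (nzchar(object$units)) object$units else "value",
                  title = object$label)
}

#' Event series (beat times, stimulus markers)
#'
#' Strictly increasing event times in recording seconds.
#'
#' @param times Numeric vector of event times (s), strictly increasing.
#' @param label Label for the event family (e.g. "beats", "hold_onset").
#' @return An object of class `hp_events`.
#' @export
event_series <- function(times, label = "") {
  times <- as.numeric(times)
  if (anyNA(times) || !all(is.finite(times)))
    abort("Event times must be finite.", class = "hp_invariant_error")
  if (length(times) > 1 && any(diff(times) <= 0))
    abort("Event times must be strictly increasing.", class = "hp_invariant_error")
  structure(list(times = times, label = as.character(label)), class = "hp_events")
}

#' @export
print.hp_events <- function(x, ...) {
  cat(sprintf("<hp_events> %s: %d events", if (nzchar(x$label)) x$label else "(unlabelled)",
              length(x$times)))
  if (length(x$times)) cat(sprintf(" in [%.3f, %.3f] s", min(x$times), max(x$times)))
  cat("\n")
  invisible(x)
}

#' @export
as_tibble.hp_events <- function(x, ...) tibble(time = x$times, label = x$label)

#' @export
length.hp_events <- function(x) length(x$times)

#' Multichannel recording
#'
#' A named collection of [timeseries()] channels plus named [event_series()]
#' marker sets and free-form metadata. Channels may have different sampling
#' rates but must cover a common time span (within one sample of the slowest
#' channel).
#'
#' @param channels Named list of `hp_ts` objects (unique names).
#' @param markers Named list of `hp_events` objects (possibly empty).
#' @param metadata Named list of scalar metadata (subject id, notes, ...).
#' @return An object of class `hp_recording`.
#' @export
recording <- function(channels, markers = list(), metadata = list()) {
  if (!length(channels)) abort("A recording needs at least one channel.", class = "hp_invariant_error")
  if (is.null(names(channels)) || any(!nzchar(names(channels))) || anyDuplicated(names(channels)))
    abort("Channel names must be present and unique.", class = "hp_format_error")
  for (ch in channels) stopifnot(inherits(ch, "hp_ts"))
  durs <- vapply(channels, ts_duration, numeric(1))
  slowest <- max(vapply(channels, function(ch) 1 / ch$fs, numeric(1)))
  if (diff(range(durs)) > slowest + 1e-9)
    abort("All channels must cover a common time span (within one sample).",
          class = "hp_invariant_error")
  if (length(markers)) {
    if (is.null(names(markers)) || anyDuplicated(names(markers)))
      abort("Marker set names must be present and unique.", class = "hp_format_error")
    for (ev in markers) stopifnot(inherits(ev, "hp_events"))
  }
  structure(list(channels = channels, markers = markers, metadata = metadata),
            class = "hp_recording")
}

#' @export
print.hp_recording <- function(x, ...) {
  cat(sprintf("<hp_recording> %d channel(s), %d marker set(s)\n",
              length(x$channels), length(x$markers)))
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %-10s %8d samples @ %6g Hz [%s]\n", nm, length(ch$samples), ch$fs, ch$units))
  }
  for (nm in names(x$markers))
    cat(sprintf("  markers %-8s %d events\n", nm, length(x$markers[[nm]]$times)))
  invisible(x)
}

#' Summary table for a recording
#' @param x An `hp_recording`.
#' @param ... Unused.
#' @return A tibble with one row per channel (name, n, fs, duration, units).
#' @export
glance.hp_recording <- function(x, ...) {
  tibble(
    channel = names(x$channels),
    n = vapply(x$channels, function(ch) length(ch$samples), integer(1)),
    fs = vapply(x$channels, function(ch) ch$fs, numeric(1)),
    duration = vapply(x$channels, ts_duration, numeric(1)),
    units = vapply(x$channels, function(ch) ch$units, character(1))
  )
}
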