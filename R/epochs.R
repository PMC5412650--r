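#' Event-locked epoching
#'
#' Cuts fixed windows (`tmin` to `tmax` seconds relative to each event) out
#' of a signal, the standard construction for averaging breath-hold
#' responses: a 5 s pre-stimulus to 80 s post-stimulus window around each
#' hold onset. Uniform [timeseries()] are epoched directly; per-beat tibbles
#' (irregular series such as transit time, heart rate or per-beat blood
#' pressure, with a time column and one value column) are first resampled to
#' a uniform grid by linear interpolation (default 4 Hz). Events whose window
#' falls partly outside the recording are dropped with a warning, never
#' padded.
#'
#' @param x A [timeseries()], or a data frame whose first column is time (s)
#'   and second column the value (e.g. output of [compute_hr()] or
#'   [estimate_bp()]).
#' @param events An [event_series()] of epoch onsets (t = 0 in epoch time).
#' @param tmin,tmax Epoch window in s relative to each event (defaults -5, 80).
#' @param fs_out Resampling rate (Hz) for irregular per-beat input (default 4).
#' @return An object of class `hp_epochs`: list with `data` (matrix,
#'   events x samples), `time` (relative axis including 0), `fs`, `label`,
#'   `n_dropped`.
#' @export
epoch_series <- function(x, events, tmin = -5, tmax = 80, fs_out = 4) {
  stopifnot(inherits(events, "hp_events"))
  if (tmax <= tmin) abort("`tmax` must exceed `tmin`.", class = "hp_param_error")

  if (inherits(x, "hp_ts")) {
    fs <- x$fs
    t0 <- x$start_time
    samples <- x$samples
    label <- x$label
  } else if (is.data.frame(x)) {
    if (ncol(x) < 2) abort("Per-beat input needs a time column and a value column.",
                           class = "hp_param_error")
    tt <- x[[1]]
    vv <- x[[2]]
    if (length(tt) < 2) abort("Per-beat input needs >= 2 points.", class = "hp_param_error")
    fs <- fs_out
    t0 <- tt[1]
    grid <- seq(tt[1], tt[length(tt)], by = 1 / fs_out)
    samples <- approx(tt, vv, xout = grid, rule = 2)$y
    label <- names(x)[2]
  } else {
    abort("`x` must be a timeseries or a per-beat data frame.", class = "hp_param_error")
  }

  n <- length(samples)
  rel_idx <- seq(floor(tmin * fs), ceiling(tmax * fs))
  rel_time <- rel_idx / fs
  rows <- list()
  kept_events <- numeric(0)
  n_dropped <- 0L
  for (ev in events$times) {
    idx <- round((ev - t0) * fs) + 1 + rel_idx
    if (idx[1] < 1 || idx[length(idx)] > n) {
      n_dropped <- n_dropped + 1L
      next
    }
    rows[[length(rows) + 1]] <- samples[idx]
    kept_events <- c(kept_events, ev)
  }
  if (n_dropped > 0)
    warn(sprintf("Dropped %d epoch(s) extending outside the recording.", n_dropped))
  if (!length(rows)) abort("No complete epochs.", class = "hp_data_error")
  structure(list(data = do.call(rbind, rows), time = rel_time, fs = fs,
                 label = label, events = kept_events, n_dropped = n_dropped),
            class = "hp_epochs")
}

#' @export
print.hp_epochs <- function(x, ...) {
  cat(sprintf("<hp_epochs> %s: %d epoch(s) x %d samples, %.1f..%.1f s @ %g Hz\n",
              x$label, nrow(x$data), ncol(x$data), min(x$time), max(x$time), x$fs))
  invisible(x)
}

#' @export
as_tibble.hp_epochs <- function(x, ...) {
  tibble(epoch = rep(seq_len(nrow(x$data)), each = ncol(x$data)),
         time = rep(x$time, nrow(x$data)),
         value = as.vector(t(x$data)))
}

#' Whole-interval baseline correction
#'
#' Subtracts each epoch's own mean over the full epoch window, so every
#' corrected epoch has zero mean. Idempotent and invariant to per-epoch
#' constant offsets.
#'
#' @param es An `hp_epochs` from [epoch_series()].
#' @return The corrected `hp_epochs`.
#' @export
baseline_correct <- function(es) {
  stopifnot(inherits(es, "hp_epochs"))
  es$data <- es$data - rowMeans(es$data)
  es
}

#' Across-epoch average with dispersion
#'
#' Pointwise mean and sample standard deviation (n - 1 denominator) across
#' epochs; `sd` is zero for a single epoch. An `include` mask supports
#' manual epoch exclusion (e.g. averaging only 4 of 5 holds) without any
#' hidden rejection rule.
#'
#' @param es An `hp_epochs`.
#' @param include Optional logical or integer mask of epochs to average.
#' @return A tibble of class `hp_avg` with columns `time`, `mean`, `sd` and
#'   attribute `n`.
#' @export
average_epochs <- function(es, include = NULL) {
  stopifnot(inherits(es, "hp_epochs"))
  dat <- es$data
  if (!is.null(include)) dat <- dat[include, , drop = FALSE]
  if (!nrow(dat)) abort("No epochs selected.", class = "hp_param_error")
  m <- colMeans(dat)
  s <- if (nrow(dat) > 1) apply(dat, 2, sd) else rep(0, ncol(dat))
  out <- tibble(time = es$time, mean = m, sd = s)
  attr(out, "n") <- nrow(dat)
  attr(out, "label") <- es$label
  class(out) <- c("hp_avg", class(out))
  out
}

#' @export
autoplot.hp_avg <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "time from event (s)",
                  y = attr(object, "label") %||% "response",
                  subtitle = sprintf("mean of %d epochs, band = +/-1 SD", attr(object, "n")))
}
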