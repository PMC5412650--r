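#' Band power by Welch's method
#'
#' Averaged-periodogram spectral estimate: the signal is split into
#' Hann-windowed segments with the stated overlap, each periodogram is
#' scaled to power spectral density (units^2/Hz, one-sided), the segments
#' are averaged, and the PSD is integrated over `band` (the full spectrum
#' when `band` is `NULL`). The full-spectrum integral of a long white-noise
#' record approaches its variance (Parseval), and a sinusoid of amplitude
#' `a` carries total power `a^2 / 2`.
#'
#' @param ts A [timeseries()] at least one segment long.
#' @param segment_length Segment length in s (default 10).
#' @param overlap Fractional overlap between segments in `[0, 1)`
#'   (default 0.5).
#' @param band Length-2 frequency band (Hz) to integrate over, or `NULL` for
#'   the full spectrum.
#' @return Band-integrated power (signal units squared), a single number.
#' @export
welch_power <- function(ts, segment_length = 10, overlap = 0.5, band = NULL) {
  psd <- welch_psd(ts, segment_length, overlap)
  df <- psd$freq[2] - psd$freq[1]
  sel <- if (is.null(band)) rep(TRUE, length(psd$freq))
         else psd$freq >= band[1] & psd$freq <= band[2]
  sum(psd$psd[sel]) * df
}

#' @rdname welch_power
#' @return `welch_psd()`: a tibble with columns `freq` (Hz) and `psd`
#'   (units^2/Hz).
#' @export
welch_psd <- function(ts, segment_length = 10, overlap = 0.5) {
  stopifnot(inherits(ts, "hp_ts"))
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1).", class = "hp_param_error")
  nseg <- round(segment_length * ts$fs)
  if (nseg > length(ts$samples))
    abort("Signal shorter than one segment.", class = "hp_param_error")
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(ts$samples) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))  # Hann
  norm <- ts$fs * sum(w^2)
  nfreq <- nseg %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- ts$samples[s:(s + nseg - 1L)] * w
    p <- Mod(fft(seg))^2 / norm
    p <- p[seq_len(nfreq)]
    # one-sided: double everything except DC (and Nyquist for even nseg)
    dbl <- rep(2, nfreq)
    dbl[1] <- 1
    if (nseg %% 2 == 0) dbl[nfreq] <- 1
    acc <- acc + p * dbl
  }
  tibble(freq = (seq_len(nfreq) - 1) * ts$fs / nseg, psd = acc / length(starts))
}

#' Device-compatibility comparison of per-channel band powers
#'
#' Reproduces the with-versus-without-device analysis: given the per-channel
#' mean band power measured with the extra devices attached (`power_with`)
#' and without (`power_without`), fits the ordinary least-squares line
#' `without ~ with` (with-device on the x axis), and reports slope,
#' intercept, Pearson R^2, and the intercept as a fraction of the mean
#' without-device power — the quantity that exposes a systematic power
#' offset introduced by the extra hardware.
#'
#' @param power_with,power_without Numeric vectors of per-channel mean
#'   powers, same length (>= 2), same channel order.
#' @param channel_groups Optional per-channel group labels (e.g. sensor
#'   type); carried into the per-channel table.
#' @return An object of class `hp_compat` with [tidy()] (per-channel table),
#'   [glance()] (slope, intercept, `pearson_r2`, `intercept_fraction`) and
#'   [autoplot()] methods.
#' @export
compare_conditions <- function(power_with, power_without, channel_groups = NULL) {
  if (length(power_with) != length(power_without))
    abort("Condition vectors must have the same channel set.", class = "hp_param_error")
  if (length(power_with) < 2)
    abort("Need >= 2 channels for a linear fit.", class = "hp_param_error")
  fit <- lm(power_without ~ power_with)
  r2 <- stats::cor(power_with, power_without)^2
  structure(list(
    table = tibble(channel = seq_along(power_with),
                   group = channel_groups %||% NA_character_,
                   power_with = power_with,
                   power_without = power_without),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    pearson_r2 = r2,
    intercept_fraction = unname(coef(fit)[1]) / mean(power_without)
  ), class = "hp_compat")
}

#' @export
print.hp_compat <- function(x, ...) {
  cat(sprintf("<hp_compat> %d channels: slope %.4f, intercept %.3g (%.2f%% of mean power), R^2 = %.4f\n",
              nrow(x$table), x$slope, x$intercept, 100 * x$intercept_fraction,
              x$pearson_r2))
  invisible(x)
}

#' @export
#' @rdname compare_conditions
#' @param x,object An `hp_compat`.
#' @param ... Unused.
tidy.hp_compat <- function(x, ...) x$table

#' @export
#' @rdname compare_conditions
glance.hp_compat <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         pearson_r2 = x$pearson_r2, intercept_fraction = x$intercept_fraction,
         n_channels = nrow(x$table))
}

#' @export
#' @rdname compare_conditions
autoplot.hp_compat <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(.data$power_with, .data$power_without)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "red") +
    ggplot2::labs(x = "mean power, devices attached",
                  y = "mean power, devices removed",
                  subtitle = sprintf("R^2 = %.4f, intercept = %.2f%% of mean power",
                                     object$pearson_r2, 100 * object$intercept_fraction))
}
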