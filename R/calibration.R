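#' Fit the transit-time to blood-pressure calibration curve
#'
#' Fits the monotone family `BP = A * PTT^(-alpha) + B` (the Gesche-style
#' per-subject calibration: pressure falls as transit time grows) against
#' reference blood-pressure readings. With `alpha` fixed (default 1) the fit
#' is linear in `(A, B)`; `alpha = NULL` requests the full three-parameter
#' nonlinear fit, initialised from a profiled grid over alpha. The fitted
#' curve must be strictly decreasing over the data range (`A > 0`), otherwise
#' a fit error is raised.
#'
#' @param ptt Per-beat transit times: an `hp_ptt` tibble from
#'   [compute_ptt()] or a bare numeric vector (s).
#' @param reference_bp Reference per-beat blood pressure (mmHg), same length.
#' @param alpha Fixed exponent (> 0), or `NULL` to estimate it.
#' @param A Optional fixed slope coefficient; with both `A` and `alpha` fixed
#'   only the offset `B` remains and a single (ptt, bp) pair suffices.
#' @return An object of class `hp_calibration` with fields `A`, `alpha`, `B`
#'   and `valid_ptt_range`; supports [tidy()], [glance()] and [predict()].
#' @export
fit_calibration <- function(ptt, reference_bp, alpha = 1, A = NULL) {
  x <- if (inherits(ptt, "hp_ptt")) ptt$ptt else as.numeric(ptt)
  y <- as.numeric(reference_bp)
  if (length(x) != length(y)) abort("`ptt` and `reference_bp` lengths differ.", class = "hp_param_error")
  if (any(x <= 0)) abort("Transit times must be positive.", class = "hp_param_error")

  if (!is.null(A)) {
    if (is.null(alpha)) abort("Fixing `A` requires a fixed `alpha`.", class = "hp_param_error")
    if (A <= 0) abort("`A` must be > 0 for a decreasing curve.", class = "hp_param_error")
    resid <- y - A * x^(-alpha)
    return(structure(list(A = A, alpha = alpha, B = mean(resid),
                          valid_ptt_range = range(x),
                          rss = sum((resid - mean(resid))^2), n = length(x)),
                     class = "hp_calibration"))
  }
  if (length(unique(x)) < 2) abort("Need >= 2 distinct transit times.", class = "hp_param_error")
  if (stats::cor(x, y) > 0)
    abort("Reference BP increases with PTT: data violate the monotone decreasing model.",
          class = "hp_fit_error")

  fit_at <- function(a) {
    z <- x^(-a)
    fit <- lm(y ~ z)
    list(A = unname(coef(fit)[2]), B = unname(coef(fit)[1]),
         rss = sum(fit$residuals^2))
  }

  if (!is.null(alpha)) {
    if (alpha <= 0) abort("`alpha` must be > 0.", class = "hp_param_error")
    est <- fit_at(alpha)
    a_hat <- alpha
  } else {
    grid <- exp(seq(log(0.25), log(4), length.out = 40))
    rss <- vapply(grid, function(a) fit_at(a)$rss, numeric(1))
    a0 <- grid[which.min(rss)]
    opt <- stats::optimize(function(a) fit_at(a)$rss,
                           interval = c(a0 / 2, a0 * 2))
    a_hat <- opt$minimum
    est <- fit_at(a_hat)
  }
  if (est$A <= 0)
    abort("Fitted curve is not strictly decreasing (A <= 0).", class = "hp_fit_error")

  structure(list(A = est$A, alpha = a_hat, B = est$B,
                 valid_ptt_range = range(x), rss = est$rss, n = length(x)),
            class = "hp_calibration")
}

#' @export
print.hp_calibration <- function(x, ...) {
  cat(sprintf("<hp_calibration> BP = %.4g * PTT^(-%.4g) + %.4g  (PTT %.0f-%.0f ms, n = %d)\n",
              x$A, x$alpha, x$B, 1000 * x$valid_ptt_range[1],
              1000 * x$valid_ptt_range[2], x$n))
  invisible(x)
}

#' @export
#' @rdname fit_calibration
#' @param x An `hp_calibration`.
#' @param ... Unused.
tidy.hp_calibration <- function(x, ...) {
  tibble(term = c("A", "alpha", "B"),
         estimate = c(x$A, x$alpha, x$B))
}

#' @export
#' @rdname fit_calibration
glance.hp_calibration <- function(x, ...) {
  tibble(rss = x$rss, n = x$n,
         ptt_min = x$valid_ptt_range[1], ptt_max = x$valid_ptt_range[2])
}

#' @export
#' @rdname fit_calibration
#' @param object An `hp_calibration`.
#' @param newdata Numeric transit times (s).
predict.hp_calibration <- function(object, newdata, ...) {
  object$A * as.numeric(newdata)^(-object$alpha) + object$B
}

#' Per-beat blood pressure from transit times
#'
#' With a calibration model, maps each transit time through
#' `BP = A * PTT^(-alpha) + B` (absolute mmHg). Without one — the common case
#' when the calibration procedure is omitted — returns a relative series: the
#' z-score of the negated transit time, so the output rises when transit time
#' falls (shorter transit = stiffer, higher-pressure artery) but carries no
#' mmHg claim. An optional centred moving average (in beats) smooths the
#' series the way averaged transit-time curves are usually displayed.
#'
#' @param ptt An `hp_ptt` tibble from [compute_ptt()].
#' @param model An `hp_calibration`, or `NULL` for relative mode.
#' @param smooth_beats Width of an optional centred moving average, in beats
#'   (0 = none).
#' @return A tibble of class `hp_bp` with columns `beat_time`, `bp` and
#'   attribute `mode` (`"absolute"` or `"relative"`).
#' @export
estimate_bp <- function(ptt, model = NULL, smooth_beats = 0) {
  stopifnot(inherits(ptt, "hp_ptt"))
  if (!nrow(ptt)) abort("Empty transit-time series.", class = "hp_param_error")
  if (!is.null(model)) {
    stopifnot(inherits(model, "hp_calibration"))
    bp <- predict(model, ptt$ptt)
    mode <- "absolute"
  } else {
    s <- sd(ptt$ptt)
    bp <- if (s > 0) -(ptt$ptt - mean(ptt$ptt)) / s else rep(0, nrow(ptt))
    mode <- "relative"
  }
  if (smooth_beats > 1) bp <- moving_average(bp, smooth_beats)
  out <- tibble(beat_time = ptt$beat_time, bp = bp)
  attr(out, "mode") <- mode
  class(out) <- c("hp_bp", class(out))
  out
}

moving_average <- function(x, w) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - w %/% 2)
    hi <- min(n, i + w %/% 2)
    mean(x[lo:hi])
  }, numeric(1))
}

#' @export
autoplot.hp_bp <- function(object, ...) {
  unit <- if (identical(attr(object, "mode"), "absolute")) "BP (mmHg)" else "relative BP (z)"
  ggplot2::ggplot(object, ggplot2::aes(.data$beat_time, .data$bp)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = unit)
}

#' Chest-to-neck transit-time blood-pressure pipeline
#'
#' The standard composition on accelerometer channels: band-pass the chest
#' channel to isolate the pulse train, detect reference beats, guide the
#' search on the neck channel, QC the beat series, compute per-beat transit
#' time and heart rate, and estimate blood pressure (relative mode unless a
#' calibration model is given).
#'
#' @param chest,distal [timeseries()] channels: the proximal reference
#'   (chest ACM) and the distal pulse channel (neck ACM).
#' @param model Optional `hp_calibration` for absolute output.
#' @param lag_window Proximal-to-distal lag window in s.
#' @param prefilter Band (Hz) applied to the reference channel before
#'   detection; `c(0.5, 30)` strips respiration and drift.
#' @param min_interval Detector refractory period (s).
#' @param smoothing Low-pass cutoff (Hz) used to suppress argmax jitter in
#'   the guided distal search; `NULL` searches raw samples.
#' @return List with `bp` (`hp_bp`), `hr`, `ptt` (`hp_ptt`), `beats`
#'   (`hp_events`) and `qc` (beat-QC report tibble).
#' @export
acm_ptt_bp <- function(chest, distal, model = NULL, lag_window = c(0.02, 0.4),
                       prefilter = c(0.5, 30), min_interval = 0.4,
                       smoothing = 15) {
  ref_ts <- if (is.null(prefilter)) chest else bandpass(chest, prefilter[1], prefilter[2])
  ref <- detect_reference_peaks(ref_ts, min_interval = min_interval,
                                smoothing_bandwidth = smoothing)
  qc <- qc_beat_series(ref)
  guided <- detect_peaks_guided(distal, qc$events,
                                lag_min = lag_window[1], lag_max = lag_window[2],
                                smoothing_bandwidth = smoothing)
  distal_ev <- event_series(sort(unique(guided$time[!is.na(guided$time)])), label = "distal")
  ptt <- compute_ptt(qc$events, distal_ev, lag_window = lag_window)
  ptt <- qc_ptt(ptt)
  list(bp = estimate_bp(ptt, model = model),
       hr = compute_hr(qc$events),
       ptt = ptt,
       beats = qc$events,
       qc = qc$report)
}

#' Match two per-beat series on shared beats
#'
#' Aligns two per-beat tibbles (e.g. the chest-based and MEG-based relative
#' blood-pressure series) by pairing each beat in `a` with the nearest beat
#' in `b` within `tol` seconds. The two proximal timebases never agree
#' exactly — a MEG artifact peak is not a chest-wall peak — so exact joins
#' are useless; tolerance matching pairs physiological beats and drops
#' detections present in only one series.
#'
#' @param a,b Tibbles with a `beat_time` column (e.g. `hp_bp` objects).
#' @param tol Maximum |time difference| for a pair, in s (default 0.15).
#' @return A tibble with `beat_time` (from `a`) and the value columns of
#'   both inputs suffixed `_a` / `_b`.
#' @export
match_beats <- function(a, b, tol = 0.15) {
  stopifnot("beat_time" %in% names(a), "beat_time" %in% names(b))
  ib <- vapply(a$beat_time, function(t) {
    j <- which.min(abs(b$beat_time - t))
    if (abs(b$beat_time[j] - t) <= tol) j else NA_integer_
  }, integer(1))
  keep <- !is.na(ib)
  va <- a[keep, setdiff(names(a), "beat_time"), drop = FALSE]
  vb <- b[ib[keep], setdiff(names(b), "beat_time"), drop = FALSE]
  names(va) <- paste0(names(va), "_a")
  names(vb) <- paste0(names(vb), "_b")
  dplyr::bind_cols(tibble(beat_time = a$beat_time[keep]), va, vb)
}

#' Blood pressure from MEG cardiac artifacts and a neck accelerometer
#'
#' The single-sensor variant: heartbeats are detected on a MEG channel (the
#' cardiac artifact it incidentally records), the neck channel supplies the
#' distal pulse, and the transit-time series is converted to relative blood
#' pressure. The MEG-to-neck transit time contains a modality-dependent
#' constant offset relative to chest-based timing (the artifact peak is not
#' the chest-wall peak); relative mode absorbs it, which is why no absolute
#' calibration is offered here.
#'
#' @param meg A MEG channel [timeseries()] containing the cardiac artifact.
#' @param neck The neck ACM [timeseries()].
#' @param lag_window MEG-to-neck lag window (s).
#' @param prefilter Band (Hz) applied to the MEG channel before detection;
#'   the default 0.5-30 Hz is the standard task band.
#' @param min_interval Detector refractory period (s).
#' @return As [acm_ptt_bp()] (relative-mode `bp`).
#' @export
meg_ptt_bp <- function(meg, neck, lag_window = c(0.02, 0.4),
                       prefilter = c(0.5, 30), min_interval = 0.4) {
  acm_ptt_bp(meg, neck, model = NULL, lag_window = lag_window,
             prefilter = prefilter, min_interval = min_interval)
}
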