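#' Per-beat pulse transit time from two beat-event series
#'
#' Pairs each proximal beat (chest ACM or MEG cardiac artifact) with the
#' unique distal event (neck pulse arrival) falling inside the lag window and
#' reports the delay. Beats with no distal candidate are dropped and counted;
#' when two candidates fall in one window the one nearest the window start
#' wins and the beat is flagged. More than 50% unmatched beats raises a
#' pairing error — that pattern means the wrong channels or window.
#'
#' @param proximal,distal [event_series()] of beat times (ideally after
#'   [qc_beat_series()]).
#' @param lag_window Length-2 numeric `(min, max)` lag in s; default
#'   `c(0.02, 0.4)`.
#' @return A tibble of class `hp_ptt` with columns `beat_time` (proximal),
#'   `ptt` (s) and `flagged` (ambiguous match), plus attributes `n_dropped`
#'   and `n_proximal`.
#' @examples
#' compute_ptt(event_series(c(1, 2)), event_series(c(1.12, 2.13)))
#' @export
compute_ptt <- function(proximal, distal, lag_window = c(0.02, 0.4)) {
  stopifnot(inherits(proximal, "hp_events"), inherits(distal, "hp_events"))
  if (lag_window[2] <= lag_window[1])
    abort("`lag_window` must be increasing.", class = "hp_param_error")
  pt <- proximal$times
  dt <- distal$times

  rows <- purrr::map(pt, function(p) {
    cand <- dt[dt > p + lag_window[1] - 1e-12 & dt < p + lag_window[2] + 1e-12]
    if (!length(cand)) return(NULL)
    tibble(beat_time = p, ptt = cand[1] - p, flagged = length(cand) > 1)
  })
  out <- dplyr::bind_rows(rows)
  n_matched <- if (is.null(out) || !nrow(out)) 0L else nrow(out)
  if (length(pt) && n_matched < 0.5 * length(pt))
    abort(sprintf("Only %d of %d proximal beats matched a distal event: wrong channels or lag window?",
                  n_matched, length(pt)), class = "hp_pairing_error")
  if (!n_matched) out <- tibble(beat_time = numeric(0), ptt = numeric(0), flagged = logical(0))
  attr(out, "n_dropped") <- length(pt) - n_matched
  attr(out, "n_proximal") <- length(pt)
  class(out) <- c("hp_ptt", class(out))
  out
}

#' MAD-based transit-time outlier rejection
#'
#' Flags and removes per-beat transit times farther than `k` median absolute
#' deviations from the series median — the automated stand-in for visually
#' vetting individual beats.
#'
#' @param ptt An `hp_ptt` tibble from [compute_ptt()].
#' @param k Outlier threshold in scaled MADs (default 5).
#' @return The filtered `hp_ptt` tibble; attribute `n_outliers` counts
#'   removals.
#' @export
qc_ptt <- function(ptt, k = 5) {
  stopifnot(inherits(ptt, "hp_ptt"))
  if (!nrow(ptt)) return(ptt)
  med <- median(ptt$ptt)
  madv <- stats::mad(ptt$ptt)
  keep <- if (madv == 0) rep(TRUE, nrow(ptt)) else abs(ptt$ptt - med) <= k * madv
  out <- ptt[keep, ]
  attr(out, "n_outliers") <- sum(!keep)
  attr(out, "n_dropped") <- attr(ptt, "n_dropped")
  attr(out, "n_proximal") <- attr(ptt, "n_proximal")
  class(out) <- unique(c("hp_ptt", class(out)))
  out
}

#' Beat-to-beat heart rate
#'
#' `HR_i = 60 / (t_{i+1} - t_i)` in bpm, anchored at the midpoint of each
#' inter-beat interval; length is one less than the number of beats.
#'
#' @param beats An [event_series()] of beat times (>= 2 events).
#' @return A tibble with columns `time` (interval midpoints, s) and `hr` (bpm).
#' @examples
#' compute_hr(event_series(seq(0, 8, by = 0.8)))
#' @export
compute_hr <- function(beats) {
  stopifnot(inherits(beats, "hp_events"))
  if (length(beats$times) < 2)
    abort("Need at least two beats for a heart rate.", class = "hp_param_error")
  tt <- beats$times
  tibble(time = (head(tt, -1) + tail(tt, -1)) / 2,
         hr = 60 / diff(tt))
}
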