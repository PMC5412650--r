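#' Simulation configuration for the synthetic multimodal session
#'
#' The simulator generates latent physiology first — blood pressure with
#' Mayer-wave (~0.1 Hz) oscillations and breath-hold ramps, instantaneous
#' heart rate with band-limited variability, respiration that is smoothly
#' suppressed during holds, and hold-locked hemoglobin transients — and then
#' renders every sensor channel from it: chest/neck accelerometers as one
#' pulse wavelet per beat (the neck wavelet delayed by the true per-beat pulse
#' transit time), a MEG channel as a cardiac-artifact wavelet train over 1/f
#' background, and two NIRS intensities through the forward modified
#' Beer-Lambert law. Per-beat transit time is tied to blood pressure through
#' the inverse of the calibration map `BP = A * PTT^(-alpha) + B`, so higher
#' pressure always means shorter transit time.
#'
#' Breath holds follow the study protocol shape: a hold lasts 30 s and the
#' default task schedule ([hold_schedule()]) repeats it five times with 30 s
#' of normal breathing in between.
#'
#' @param duration Session length in seconds (> 0).
#' @param fs Sampling rate of rendered sensor channels (Hz); 1 kHz default.
#' @param fs_latent Sampling rate of the stored latent series (Hz).
#' @param seed Integer seed; `(config, seed)` fully determine all outputs.
#' @param baseline_hr Mean heart rate (bpm).
#' @param hr_variability_sd SD of band-limited heart-rate variability (bpm).
#' @param baseline_map Baseline mean arterial pressure (mmHg).
#' @param mayer_amplitude,mayer_frequency Amplitude (mmHg) and frequency (Hz)
#'   of the Mayer-wave blood-pressure oscillation.
#' @param respiration_rate Breathing rate (Hz).
#' @param respiration_amplitude Respiration component amplitude on the chest
#'   channel, relative to pulse amplitude 1.
#' @param breath_hold_schedule Tibble/data frame with columns `onset`,
#'   `duration` (s); `NULL` for no holds. Holds must be non-overlapping and
#'   inside `[0, duration]`.
#' @param bp_hold_ramp Blood-pressure rise reached by the end of a hold (mmHg);
#'   linear ramp during the hold, exponential relaxation (`bp_relax_tau` s)
#'   afterwards.
#' @param bp_relax_tau Post-hold blood-pressure relaxation constant (s).
#' @param hr_hold_drop Heart-rate decrease during a hold (bpm).
#' @param hbo_hold_dip Magnitude of the transient HbO decrease during a hold (uM).
#' @param hb_hold_rise Magnitude of the slight Hb increase during a hold (uM).
#' @param pulse_amplitude_chest,pulse_amplitude_neck Pulse wavelet amplitudes.
#' @param pulse_sigma Pulse wavelet width (s, Gaussian sigma).
#' @param pulse_shape `"gaussian"` (peak at beat time) or `"dgaussian"`
#'   (Gaussian derivative).
#' @param noise_chest,noise_neck Additive white-noise SD on the ACM channels.
#' @param meg_artifact_amplitude Cardiac-artifact wavelet amplitude on the MEG
#'   channel.
#' @param meg_artifact_sigma MEG artifact wavelet width (s).
#' @param meg_background_sd SD of the 1/f-shaped MEG background.
#' @param meg_background_exponent Spectral exponent of the background
#'   (power ~ 1/f^exponent).
#' @param nirs_i0 Baseline detected intensity (a.u.) for both wavelengths.
#' @param nirs_noise Multiplicative intensity noise SD (fraction of intensity).
#' @param calibration List `(A, alpha, B)` of the true coupling
#'   `BP = A * PTT^(-alpha) + B` used to derive per-beat transit times.
#' @return An object of class `hp_sim_config` (validated list).
#' @examples
#' cfg <- sim_config(duration = 30, seed = 7)
#' sim <- simulate_recording(cfg)
#' glance(sim$recording)
#' @export
sim_config <- function(duration = 120,
                       fs = 1000,
                       fs_latent = 100,
                       seed = 1,
                       baseline_hr = 60,
                       hr_variability_sd = 3,
                       baseline_map = 90,
                       mayer_amplitude = 5,
                       mayer_frequency = 0.1,
                       respiration_rate = 0.25,
                       respiration_amplitude = 0.3,
                       breath_hold_schedule = NULL,
                       bp_hold_ramp = 10,
                       bp_relax_tau = 10,
                       hr_hold_drop = 3,
                       hbo_hold_dip = 1,
                       hb_hold_rise = 0.2,
                       pulse_amplitude_chest = 1,
                       pulse_amplitude_neck = 1,
                       pulse_sigma = 0.025,
                       pulse_shape = c("gaussian", "dgaussian"),
                       noise_chest = 0.05,
                       noise_neck = 0.05,
                       meg_artifact_amplitude = 1,
                       meg_artifact_sigma = 0.015,
                       meg_background_sd = 0.3,
                       meg_background_exponent = 1,
                       nirs_i0 = 1,
                       nirs_noise = 0.001,
                       calibration = list(A = 7.5, alpha = 1, B = 40)) {
  pulse_shape <- match.arg(pulse_shape)
  if (duration <= 0) abort("`duration` must be > 0.", class = "hp_config_error")
  amps <- c(hr_variability_sd, mayer_amplitude, respiration_amplitude, bp_hold_ramp,
            hbo_hold_dip, hb_hold_rise, pulse_amplitude_chest, pulse_amplitude_neck,
            noise_chest, noise_neck, meg_artifact_amplitude, meg_background_sd,
            nirs_noise)
  if (any(amps < 0)) abort("Amplitudes and noise levels must be >= 0.", class = "hp_config_error")
  if (!is.null(breath_hold_schedule)) {
    bh <- as_tibble(breath_hold_schedule)
    if (!all(c("onset", "duration") %in% names(bh)))
      abort("`breath_hold_schedule` needs columns onset, duration.", class = "hp_config_error")
    bh <- dplyr::arrange(bh, .data$onset)
    if (any(bh$onset < 0) || any(bh$onset + bh$duration > duration))
      abort("Breath holds must lie inside [0, duration].", class = "hp_config_error")
    if (nrow(bh) > 1 && any(bh$onset[-1] < (bh$onset + bh$duration)[-nrow(bh)]))
      abort("Breath holds must not overlap.", class = "hp_config_error")
    breath_hold_schedule <- bh
  }
  if (!all(c("A", "alpha", "B") %in% names(calibration)) ||
      calibration$A <= 0 || calibration$alpha <= 0)
    abort("`calibration` must supply A > 0, alpha > 0, B.", class = "hp_config_error")
  cfg <- as.list(environment())
  structure(cfg, class = "hp_sim_config")
}

#' Breath-hold task schedule
#'
#' The default protocol: `n` holds of `hold` seconds separated by `rest`
#' seconds of normal breathing, the first hold starting at `first_onset`.
#'
#' @param n Number of holds (default 5).
#' @param hold Hold duration in s (default 30).
#' @param rest Normal-breathing gap between holds in s (default 30).
#' @param first_onset Onset of the first hold in s.
#' @return Tibble with columns `onset`, `duration`.
#' @export
hold_schedule <- function(n = 5, hold = 30, rest = 30, first_onset = 30) {
  tibble(onset = first_onset + (seq_len(n) - 1) * (hold + rest), duration = hold)
}

# Smooth 0->1->0 gate over a hold with raised-cosine edges.
hold_gate <- function(t, onset, offset, edge = 2) {
  up <- ifelse(t < onset, 0,
        ifelse(t < onset + edge, 0.5 - 0.5 * cos(pi * (t - onset) / edge), 1))
  down <- ifelse(t < offset, 1,
          ifelse(t < offset + edge, 0.5 + 0.5 * cos(pi * (t - offset) / edge), 0))
  up * down
}

# Linear ramp during the hold, exponential relaxation after it.
hold_ramp <- function(t, onset, offset, tau) {
  ifelse(t < onset, 0,
  ifelse(t <= offset, (t - onset) / (offset - onset),
         exp(-(t - offset) / tau)))
}

#' Simulate latent ground-truth physiology
#'
#' Generates the latent state every renderer and every recovery test refers
#' back to: blood pressure (baseline + Mayer sinusoid + hold ramps), heart
#' rate (baseline + band-limited variability - hold drop), beat times by
#' integrating the instantaneous rate to unit threshold, per-beat true pulse
#' transit time as the inverse calibration map evaluated at the beat-time
#' blood pressure, respiration smoothly gated off during holds, and the
#' hold-locked HbO/Hb transients.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `hp_ground_truth` with elements `bp`, `hr`,
#'   `respiration`, `hbo`, `hb` (latent [timeseries()]), `beat_times`
#'   ([event_series()]), `true_ptt` (per-beat seconds), and `funs` (exact
#'   evaluators of the latent trajectories).
#' @export
simulate_ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "hp_sim_config"))
  set.seed(cfg$seed)
  dt <- 1 / cfg$fs_latent
  tg <- seq(0, cfg$duration - dt, by = dt)
  holds <- cfg$breath_hold_schedule

  sum_holds <- function(t, f) {
    out <- numeric(length(t))
    if (!is.null(holds)) {
      for (i in seq_len(nrow(holds)))
        out <- out + f(t, holds$onset[i], holds$onset[i] + holds$duration[i])
    }
    out
  }

  bp_fun <- function(t) {
    cfg$baseline_map +
      cfg$mayer_amplitude * sin(2 * pi * cfg$mayer_frequency * t) +
      cfg$bp_hold_ramp * sum_holds(t, function(t, a, b) hold_ramp(t, a, b, cfg$bp_relax_tau))
  }

  # band-limited HRV: low-passed white noise rescaled to the target SD
  hrv_grid <- if (cfg$hr_variability_sd > 0) {
    w <- rnorm(length(tg))
    bf <- signal::butter(2, min(0.1 / (cfg$fs_latent / 2), 0.99), type = "low")
    sm <- signal::filtfilt(bf, w)
    sm <- sm / max(sd(sm), 1e-12) * cfg$hr_variability_sd
    sm
  } else numeric(length(tg))
  hrv_fun <- stats::approxfun(tg, hrv_grid, rule = 2)

  hr_fun <- function(t) {
    pmax(30, cfg$baseline_hr + hrv_fun(t) -
           cfg$hr_hold_drop * sum_holds(t, function(t, a, b) hold_gate(t, a, b)))
  }

  resp_fun <- function(t) {
    gate <- pmin(1, sum_holds(t, function(t, a, b) hold_gate(t, a, b)))
    sin(2 * pi * cfg$respiration_rate * t) * (1 - gate)
  }

  hbo_fun <- function(t) -cfg$hbo_hold_dip * sum_holds(t, function(t, a, b) hold_gate(t, a, b))
  hb_fun <- function(t) cfg$hb_hold_rise * sum_holds(t, function(t, a, b) hold_gate(t, a, b))

  # beats: integrate instantaneous rate (beats/s) to unit threshold
  rate <- hr_fun(tg) / 60
  cum <- (cumsum(rate) - rate[1]) * dt
  n_beats <- floor(max(cum))
  beat_times <- approx(x = cum, y = tg, xout = seq_len(n_beats))$y

  cal <- cfg$calibration
  ptt_of_bp <- function(bp) ((bp - cal$B) / cal$A)^(-1 / cal$alpha)
  true_ptt <- ptt_of_bp(bp_fun(beat_times))

  gt <- list(
    bp = timeseries(bp_fun(tg), cfg$fs_latent, label = "bp", units = "mmHg"),
    hr = timeseries(hr_fun(tg), cfg$fs_latent, label = "hr", units = "bpm"),
    respiration = timeseries(resp_fun(tg), cfg$fs_latent, label = "respiration", units = "a.u."),
    hbo = timeseries(hbo_fun(tg), cfg$fs_latent, label = "hbo", units = "uM"),
    hb = timeseries(hb_fun(tg), cfg$fs_latent, label = "hb", units = "uM"),
    beat_times = event_series(beat_times, label = "beats"),
    true_ptt = true_ptt,
    funs = list(bp = bp_fun, hr = hr_fun, respiration = resp_fun,
                hbo = hbo_fun, hb = hb_fun, ptt_of_bp = ptt_of_bp),
    cfg = cfg
  )
  class(gt) <- "hp_ground_truth"

  stopifnot(all(true_ptt > 0.02 & true_ptt < 0.5),
            all(bp_fun(tg) > 40 & bp_fun(tg) < 220))
  gt
}

#' @export
print.hp_ground_truth <- function(x, ...) {
  cat(sprintf("<hp_ground_truth> %.0f s, %d beats, BP %.1f-%.1f mmHg, PTT %.0f-%.0f ms\n",
              ts_duration(x$bp), length(x$beat_times$times),
              min(x$bp$samples), max(x$bp$samples),
              1000 * min(x$true_ptt), 1000 * max(x$true_ptt)))
  invisible(x)
}

#' Per-beat ground truth as a tibble
#' @param x An `hp_ground_truth`.
#' @param ... Unused.
#' @return Tibble with `beat_time`, `true_ptt`, `bp`, `hr` at beat times.
#' @export
tidy.hp_ground_truth <- function(x, ...) {
  tibble(beat_time = x$beat_times$times,
         true_ptt = x$true_ptt,
         bp = x$funs$bp(x$beat_times$times),
         hr = x$funs$hr(x$beat_times$times))
}

pulse_kernel <- function(fs, sigma, shape = "gaussian", halfwidth = 4) {
  u <- seq(-halfwidth * sigma, halfwidth * sigma, by = 1 / fs)
  k <- switch(shape,
    gaussian = exp(-u^2 / (2 * sigma^2)),
    dgaussian = {
      g <- -u * exp(-u^2 / (2 * sigma^2))
      g / max(abs(g))
    },
    abort(sprintf("Unknown pulse shape '%s'.", shape), class = "hp_config_error"))
  k
}

# Wavelet train: one kernel per event, centred at the nearest sample.
wavelet_train <- function(times, n, fs, kernel) {
  x <- numeric(n)
  idx <- round(times * fs) + 1L
  idx <- idx[idx >= 1 & idx <= n]
  x[idx] <- 1
  half <- (length(kernel) - 1L) %/% 2L
  y <- stats::convolve(x, rev(kernel), type = "open")
  y[(half + 1L):(half + n)]
}

onef_noise <- function(n, exponent, sd_target) {
  if (sd_target <= 0) return(numeric(n))
  m <- stats::nextn(n, 2)
  w <- rnorm(m)
  W <- fft(w)
  f <- c(1, seq_len(m - 1))          # avoid f = 0 blow-up; DC zeroed below
  f <- pmin(f, m - f + 1)            # symmetric (two-sided) frequency index
  scale <- f^(-exponent / 2)
  scale[1] <- 0
  x <- Re(fft(W * scale, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x / max(sd(x), 1e-12) * sd_target
}

#' Render the chest accelerometer channel
#'
#' One stereotyped pulse wavelet per beat (centred at the beat time) plus the
#' respiration component and white noise — the chest sensor sees both the
#' heartbeat-driven chest-wall motion and breathing.
#'
#' @param gt An `hp_ground_truth`.
#' @param cfg The [sim_config()] used to create `gt` (defaults to `gt$cfg`).
#' @return An [timeseries()] at `cfg$fs`.
#' @export
render_chest_acm <- function(gt, cfg = gt$cfg) {
  set.seed(cfg$seed + 101L)
  n <- round(cfg$duration * cfg$fs)
  tg <- (seq_len(n) - 1) / cfg$fs
  k <- pulse_kernel(cfg$fs, cfg$pulse_sigma, cfg$pulse_shape)
  x <- cfg$pulse_amplitude_chest * wavelet_train(gt$beat_times$times, n, cfg$fs, k) +
    cfg$respiration_amplitude * gt$funs$respiration(tg) +
    rnorm(n, sd = cfg$noise_chest)
  timeseries(x, cfg$fs, label = "chest", units = "a.u.")
}

#' Render the neck accelerometer channel
#'
#' One pulse wavelet per beat, delayed by that beat's true pulse transit time
#' (the carotid pulse arrives PTT after the proximal cardiac event), plus
#' white noise.
#'
#' @inheritParams render_chest_acm
#' @return An [timeseries()] at `cfg$fs`.
#' @export
render_neck_acm <- function(gt, cfg = gt$cfg) {
  set.seed(cfg$seed + 202L)
  n <- round(cfg$duration * cfg$fs)
  k <- pulse_kernel(cfg$fs, cfg$pulse_sigma, cfg$pulse_shape)
  x <- cfg$pulse_amplitude_neck *
    wavelet_train(gt$beat_times$times + gt$true_ptt, n, cfg$fs, k) +
    rnorm(n, sd = cfg$noise_neck)
  timeseries(x, cfg$fs, label = "neck", units = "a.u.")
}

#' Render a MEG channel carrying the cardiac artifact
#'
#' A sharper cardiac-artifact wavelet at each beat time, superposed on
#' 1/f-shaped background noise (spectrally shaped white noise).
#'
#' @inheritParams render_chest_acm
#' @return An [timeseries()] at `cfg$fs`.
#' @export
render_meg_channel <- function(gt, cfg = gt$cfg) {
  set.seed(cfg$seed + 303L)
  n <- round(cfg$duration * cfg$fs)
  k <- pulse_kernel(cfg$fs, cfg$meg_artifact_sigma, "gaussian")
  x <- cfg$meg_artifact_amplitude * wavelet_train(gt$beat_times$times, n, cfg$fs, k) +
    onef_noise(n, cfg$meg_background_exponent, cfg$meg_background_sd)
  timeseries(x, cfg$fs, label = "meg", units = "a.u.")
}

#' Render dual-wavelength NIRS intensities (forward Beer-Lambert)
#'
#' Applies the forward modified Beer-Lambert law to the latent hemoglobin
#' trajectories: `dOD(lambda, t) = (e_HbO(lambda) dHbO + e_Hb(lambda) dHb) * d * DPF(lambda)`
#' and `I = I0 * 10^(-dOD)`, with optional multiplicative noise.
#'
#' @inheritParams render_chest_acm
#' @param geom A [nirs_geometry()]; defaults match the recording setup
#'   (660/850 nm, 3 cm source-detector distance).
#' @return Named list of two [timeseries()]: `nirs660`, `nirs850`.
#' @export
render_nirs <- function(gt, cfg = gt$cfg, geom = nirs_geometry()) {
  set.seed(cfg$seed + 404L)
  n <- round(cfg$duration * cfg$fs)
  tg <- (seq_len(n) - 1) / cfg$fs
  hbo <- gt$funs$hbo(tg)
  hb <- gt$funs$hb(tg)
  out <- list()
  for (i in 1:2) {
    dod <- (geom$extinction[i, "hbo"] * hbo + geom$extinction[i, "hb"] * hb) *
      geom$distance * geom$dpf[i]
    intensity <- cfg$nirs_i0 * 10^(-dod)
    if (cfg$nirs_noise > 0)
      intensity <- intensity * (1 + rnorm(n, sd = cfg$nirs_noise))
    lab <- paste0("nirs", geom$wavelengths[i])
    out[[lab]] <- timeseries(intensity, cfg$fs, label = lab, units = "a.u.")
  }
  out
}

#' Simulate a complete multimodal recording
#'
#' Runs [simulate_ground_truth()] and all channel renderers, assembling a
#' [recording()] with channels `chest`, `neck`, `meg`, `nirs660`, `nirs850`
#' and (when a hold schedule is configured) `hold_onset` markers.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `recording` and `ground_truth`.
#' @export
simulate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "hp_sim_config"))
  gt <- simulate_ground_truth(cfg)
  nirs <- render_nirs(gt, cfg)
  channels <- c(list(chest = render_chest_acm(gt, cfg),
                     neck = render_neck_acm(gt, cfg),
                     meg = render_meg_channel(gt, cfg)),
                nirs)
  markers <- list()
  if (!is.null(cfg$breath_hold_schedule))
    markers$hold_onset <- event_series(cfg$breath_hold_schedule$onset, label = "hold_onset")
  list(recording = recording(channels, markers = markers,
                             metadata = list(simulated = TRUE, seed = cfg$seed)),
       ground_truth = gt)
}
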