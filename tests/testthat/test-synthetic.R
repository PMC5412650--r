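test_that("degenerate constant configuration gives metronome beats and flat truth", {
  cfg <- sim_config(duration = 30, seed = 1, baseline_hr = 60,
                    hr_variability_sd = 0, mayer_amplitude = 0)
  gt <- simulate_ground_truth(cfg)
  expect_equal(diff(gt$beat_times$times), rep(1, length(gt$beat_times$times) - 1),
               tolerance = 1e-9)
  expect_equal(sd(gt$bp$samples), 0)
  expect_equal(sd(gt$true_ptt), 0)
  # constant BP maps to the constant inverse-calibration transit time
  expect_equal(unique(gt$true_ptt),
               (cfg$calibration$A / (cfg$baseline_map - cfg$calibration$B)),
               tolerance = 1e-12)
})

test_that("config and seed fully determine the outputs", {
  cfg <- sim_config(duration = 20, seed = 11)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$channels$chest$samples, b$recording$channels$chest$samples)
  expect_identical(a$recording$channels$meg$samples, b$recording$channels$meg$samples)
  expect_identical(a$ground_truth$beat_times$times, b$ground_truth$beat_times$times)
})

test_that("seeds change the beat jitter but not the configured means", {
  seeds <- 1:20
  mean_hr <- vapply(seeds, function(s) {
    gt <- simulate_ground_truth(sim_config(duration = 60, seed = s))
    60 / mean(diff(gt$beat_times$times))
  }, numeric(1))
  expect_gt(sd(mean_hr), 0)  # different jitter across seeds
  se <- sd(mean_hr) / sqrt(length(seeds))
  expect_lt(abs(mean(mean_hr) - 60), 3 * se + 0.5)
  # each seed's mean within 3 SD of the across-seed spread
  expect_true(all(abs(mean_hr - mean(mean_hr)) <= 3 * sd(mean_hr) + 1e-9))
})

test_that("a blood-pressure ramp forces transit time strictly down", {
  cfg <- sim_config(duration = 120, seed = 2, mayer_amplitude = 0,
                    hr_variability_sd = 0,
                    breath_hold_schedule = data.frame(onset = 40, duration = 30))
  gt <- simulate_ground_truth(cfg)
  inside <- gt$beat_times$times > 41 & gt$beat_times$times < 69
  expect_gt(sum(inside), 10)
  expect_true(all(diff(gt$funs$bp(gt$beat_times$times[inside])) > 0))
  expect_true(all(diff(gt$true_ptt[inside]) < 0))
})

test_that("noise-free renders place every wavelet peak at its true time", {
  cfg <- sim_config(duration = 40, seed = 3, noise_chest = 0, noise_neck = 0,
                    respiration_amplitude = 0)
  gt <- simulate_ground_truth(cfg)
  chest <- render_chest_acm(gt, cfg)
  neck <- render_neck_acm(gt, cfg)
  tb <- gt$beat_times$times

  # brute-force argmax within +/-150 ms of each beat recovers the beat time
  chest_peaks <- oracle_guided_argmax(chest, tb, -0.15, 0.15)
  expect_lte(max(abs(chest_peaks - tb)), 1 / cfg$fs)

  # neck - chest peak delay equals the true transit time to <= 2 samples
  neck_peaks <- oracle_guided_argmax(neck, tb, 0.02, 0.4)
  delay <- neck_peaks - chest_peaks
  expect_lte(max(abs(delay - gt$true_ptt)), 2 / cfg$fs)
})

test_that("the respiration component survives a 0.5 Hz low-pass almost unchanged", {
  cfg <- sim_config(duration = 60, seed = 4, pulse_amplitude_chest = 0,
                    noise_chest = 0, respiration_amplitude = 1)
  gt <- simulate_ground_truth(cfg)
  chest <- render_chest_acm(gt, cfg)
  lp <- bandpass(chest, 0, 0.5)
  truth <- gt$funs$respiration(ts_time(lp))
  expect_gt(cor(lp$samples, truth), 0.99)
})

test_that("all-zero amplitudes render silence", {
  cfg <- sim_config(duration = 10, seed = 5, pulse_amplitude_chest = 0,
                    pulse_amplitude_neck = 0, noise_chest = 0, noise_neck = 0,
                    respiration_amplitude = 0, meg_artifact_amplitude = 0,
                    meg_background_sd = 0)
  gt <- simulate_ground_truth(cfg)
  expect_equal(max(abs(render_chest_acm(gt, cfg)$samples)), 0)
  expect_equal(max(abs(render_neck_acm(gt, cfg)$samples)), 0)
  expect_equal(max(abs(render_meg_channel(gt, cfg)$samples)), 0)
})

test_that("MEG artifact without background peaks exactly at beat samples", {
  cfg <- sim_config(duration = 30, seed = 6, meg_background_sd = 0)
  gt <- simulate_ground_truth(cfg)
  meg <- render_meg_channel(gt, cfg)
  peaks <- oracle_guided_argmax(meg, gt$beat_times$times, -0.1, 0.1)
  expect_lte(max(abs(peaks - gt$beat_times$times)), 1 / cfg$fs)
})

test_that("guided detection recovers >= 95% of beats from MEG at default SNR", {
  cfg <- sim_config(duration = 60, seed = 7)
  gt <- simulate_ground_truth(cfg)
  meg <- bandpass(render_meg_channel(gt, cfg), 0.5, 30)
  det <- detect_reference_peaks(meg, smoothing_bandwidth = 15)
  expect_gte(recovery_rate(det$times, gt$beat_times$times, tol = 0.02), 0.95)
})

test_that("without the artifact the detector is not beat-locked above chance", {
  cfg <- sim_config(duration = 60, seed = 8, meg_artifact_amplitude = 0)
  gt <- simulate_ground_truth(cfg)
  meg <- bandpass(render_meg_channel(gt, cfg), 0.5, 30)
  det <- detect_reference_peaks(meg, smoothing_bandwidth = 15)
  locked <- recovery_rate(det$times, gt$beat_times$times, tol = 0.02)
  # permutation comparison: recovery vs circularly shifted beat times
  withr::local_seed(1)
  null_rates <- vapply(1:50, function(i) {
    shift <- runif(1, 5, 55)
    shifted <- sort((gt$beat_times$times + shift) %% 60)
    recovery_rate(det$times, shifted, tol = 0.02)
  }, numeric(1))
  expect_lte(locked, quantile(null_rates, 0.95) + 0.1)
})

test_that("NIRS forward render inverts exactly at zero noise", {
  cfg <- sim_config(duration = 40, seed = 9, nirs_noise = 0,
                    breath_hold_schedule = data.frame(onset = 10, duration = 15))
  gt <- simulate_ground_truth(cfg)
  nirs <- render_nirs(gt, cfg)

  # flat hemoglobin gives constant intensity
  cfg0 <- sim_config(duration = 10, seed = 9, nirs_noise = 0)
  gt0 <- simulate_ground_truth(cfg0)
  nirs0 <- render_nirs(gt0, cfg0)
  expect_equal(sd(nirs0$nirs660$samples), 0)
  expect_equal(mean(nirs0$nirs660$samples), cfg0$nirs_i0)

  od1 <- compute_delta_od(nirs$nirs660, baseline_window = c(0, 5))
  od2 <- compute_delta_od(nirs$nirs850, baseline_window = c(0, 5))
  hemo <- mbll_inverse(od1, od2)
  tt <- ts_time(nirs$nirs660)
  expect_lte(max(abs(hemo$hbo - gt$funs$hbo(tt))), 1e-6)
  expect_lte(max(abs(hemo$hb - gt$funs$hb(tt))), 1e-6)
})

test_that("noisy NIRS recovery is unbiased and tightens with averaging", {
  err_by_seed <- vapply(1:12, function(s) {
    cfg <- sim_config(duration = 30, seed = 100 + s, fs = 200, nirs_noise = 0.02,
                      breath_hold_schedule = data.frame(onset = 5, duration = 20))
    gt <- simulate_ground_truth(cfg)
    nirs <- render_nirs(gt, cfg)
    hemo <- mbll_inverse(compute_delta_od(nirs$nirs660, baseline_window = c(0, 2)),
                         compute_delta_od(nirs$nirs850, baseline_window = c(0, 2)))
    short <- hemo$time >= 15 & hemo$time <= 16
    long <- hemo$time >= 10 & hemo$time <= 24
    c(short = mean(hemo$hbo[short]) - mean(gt$funs$hbo(hemo$time[short])),
      long = mean(hemo$hbo[long]) - mean(gt$funs$hbo(hemo$time[long])))
  }, numeric(2))
  # unbiased: the long-window mean error sits near zero
  expect_lt(abs(mean(err_by_seed["long", ])), 0.05)
  # averaging more samples tightens the across-seed spread
  expect_lt(sd(err_by_seed["long", ]), sd(err_by_seed["short", ]))
})

test_that("invalid configurations are refused", {
  expect_error(sim_config(duration = -5), class = "hp_config_error")
  expect_error(sim_config(mayer_amplitude = -1), class = "hp_config_error")
  expect_error(sim_config(duration = 100,
                          breath_hold_schedule = data.frame(onset = c(10, 30),
                                                            duration = c(30, 10))),
               class = "hp_config_error")
  expect_error(sim_config(duration = 50,
                          breath_hold_schedule = data.frame(onset = 40, duration = 30)),
               class = "hp_config_error")
})
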