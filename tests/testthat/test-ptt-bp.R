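test_that("transit times are direct differences of matched beat pairs", {
  ptt <- compute_ptt(event_series(c(1.0, 2.0)), event_series(c(1.12, 2.13)),
                     lag_window = c(0.02, 0.4))
  expect_equal(ptt$ptt, c(0.12, 0.13))
  expect_equal(attr(ptt, "n_dropped"), 0L)

  # distal missing the 2nd event: one transit time, one counted drop
  ptt2 <- compute_ptt(event_series(c(1.0, 2.0)), event_series(1.12),
                      lag_window = c(0.02, 0.4))
  expect_equal(nrow(ptt2), 1L)
  expect_equal(attr(ptt2, "n_dropped"), 1L)
})

test_that("matching equals the naive all-pairs oracle on random small instances", {
  withr::local_seed(30)
  for (i in 1:25) {
    prox <- sort(runif(sample(3:10, 1), 0, 20))
    prox <- prox[c(TRUE, diff(prox) > 1e-3)]
    dist <- sort(c(prox + runif(length(prox), 0.03, 0.35),
                   runif(sample(0:4, 1), 0, 20)))
    dist <- dist[c(TRUE, diff(dist) > 1e-3)]
    win <- c(0.02, 0.4)
    got <- compute_ptt(event_series(prox), event_series(dist), win)
    want <- oracle_ptt_match(prox, dist, win)
    expect_equal(got$beat_time, want$beat_time)
    expect_equal(got$ptt, want$ptt)
  }
})

test_that("mostly unmatched beats raise a pairing error", {
  expect_error(
    compute_ptt(event_series(c(1, 2, 3, 4)), event_series(c(1.1)),
                lag_window = c(0.02, 0.4)),
    class = "hp_pairing_error")
})

test_that("heart rate is 60 over the inter-beat interval, at midpoints", {
  hr <- compute_hr(event_series(seq(0, 8, by = 0.8)))
  expect_equal(hr$hr, rep(75, 10))
  expect_equal(hr$time[1], 0.4)
  hr2 <- compute_hr(event_series(0:10))
  expect_equal(hr2$hr, rep(60, 10))
  expect_equal(nrow(hr2), 10L)  # one less than the number of beats
})

test_that("calibration recovers exact generating parameters (inverse crime)", {
  x <- seq(0.08, 0.3, length.out = 40)
  y <- 700 * x^(-1) + 40
  fit <- fit_calibration(x, y, alpha = 1)
  expect_lt(abs(fit$A - 700) / 700, 1e-6)
  expect_lt(abs(fit$B - 40) / 40, 1e-6)

  # full three-parameter fit
  y2 <- 12 * x^(-1.3) + 55
  fit2 <- fit_calibration(x, y2, alpha = NULL)
  expect_lt(abs(fit2$alpha - 1.3), 1e-3)
  expect_lt(abs(fit2$A - 12) / 12, 1e-2)
  expect_lt(abs(fit2$B - 55) / 55, 1e-2)
})

test_that("one pair with fixed A and alpha pins down the offset exactly", {
  fit <- fit_calibration(0.15, 90, alpha = 1, A = 7.5)
  expect_equal(fit$B, 90 - 7.5 / 0.15)
  expect_equal(predict(fit, 0.15), 90)
})

test_that("increasing pressure-vs-transit-time data is a fit error", {
  x <- seq(0.1, 0.3, length.out = 10)
  expect_error(fit_calibration(x, 100 + 50 * x), class = "hp_fit_error")
})

test_that("the fitted curve is strictly decreasing across random valid draws", {
  withr::local_seed(31)
  grid <- seq(0.05, 0.4, length.out = 50)
  for (i in 1:20) {
    A <- runif(1, 2, 30); alpha <- runif(1, 0.5, 2); B <- runif(1, 20, 70)
    y <- A * grid^(-alpha) + B
    fit <- fit_calibration(grid, y, alpha = alpha)
    expect_lt(abs(fit$A - A) / A, 1e-6)
    expect_lt(abs(fit$B - B) / max(abs(B), 1), 1e-6)
    expect_true(all(diff(predict(fit, grid)) < 0))
  }
})

test_that("blood-pressure estimation follows the closed-form map", {
  model <- fit_calibration(c(0.1, 0.2), c(115, 77.5), alpha = 1)  # A=7.5, B=40
  ptt <- structure(tibble::tibble(beat_time = 1:3, ptt = c(0.1, 0.1, 0.1),
                                  flagged = FALSE),
                   class = c("hp_ptt", class(tibble::tibble())))
  bp <- estimate_bp(ptt, model)
  expect_equal(unique(bp$bp), 7.5 / 0.1 + 40)
  expect_identical(attr(bp, "mode"), "absolute")

  # halving the transit time doubles the A-term (alpha = 1)
  expect_equal(predict(model, 0.05) - 40, 2 * (predict(model, 0.1) - 40))
})

test_that("relative mode rises when transit time falls and is unit-scaled", {
  ptt <- structure(tibble::tibble(beat_time = 1:50,
                                  ptt = seq(0.2, 0.1, length.out = 50),
                                  flagged = FALSE),
                   class = c("hp_ptt", class(tibble::tibble())))
  bp <- estimate_bp(ptt)
  expect_identical(attr(bp, "mode"), "relative")
  expect_true(all(diff(bp$bp) > 0))
  expect_equal(mean(bp$bp), 0)
  expect_equal(sd(bp$bp), 1)
})

test_that("MAD outlier rejection removes only the planted outlier", {
  withr::local_seed(32)
  ptt <- compute_ptt(event_series(1:40),
                     event_series(1:40 + c(rep(0.12, 20), 0.35, rep(0.12, 19)) +
                                    rnorm(40, sd = 1e-3)),
                     lag_window = c(0.02, 0.4))
  out <- qc_ptt(ptt, k = 5)
  expect_equal(attr(out, "n_outliers"), 1L)
  expect_true(all(abs(out$ptt - 0.12) < 0.05))
})

test_that("simulated transit times match the ground truth closely", {
  cfg <- sim_config(duration = 120, seed = 33)
  sim <- simulate_recording(cfg)
  gt <- sim$ground_truth
  res <- acm_ptt_bp(sim$recording$channels$chest, sim$recording$channels$neck)
  tt <- tidy(gt)
  idx <- vapply(res$ptt$beat_time, function(t) which.min(abs(tt$beat_time - t)), integer(1))
  expect_lte(mean(abs(res$ptt$ptt - tt$true_ptt[idx])), 0.003)
  expect_lte(sqrt(mean((res$ptt$ptt - tt$true_ptt[idx])^2)), 0.003)
})

test_that("noise-free MEG and chest proximal channels give identical transit times", {
  cfg <- sim_config(duration = 60, seed = 34, noise_chest = 0, noise_neck = 0,
                    respiration_amplitude = 0, meg_background_sd = 0)
  sim <- simulate_recording(cfg)
  chest_res <- acm_ptt_bp(sim$recording$channels$chest, sim$recording$channels$neck)
  meg_res <- meg_ptt_bp(sim$recording$channels$meg, sim$recording$channels$neck)
  m <- match_beats(chest_res$ptt, meg_res$ptt)
  expect_gt(nrow(m), 50)
  offset <- m$ptt_b - m$ptt_a
  # constant modality offset only (here zero by construction): no spread
  expect_lte(max(offset) - min(offset), 2e-3)
})
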