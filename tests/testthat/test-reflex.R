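fs <- 20000

test_that("band-pass rejects DC, passes the band, attenuates the stopband", {
  t <- seq(0, 1, by = 1 / fs)
  win <- 2000:18000
  # constant input -> ~0
  dc <- bandpass_emg(emg_trace(rep(3, fs), fs))$samples
  expect_lt(max(abs(dc[win])), 1e-6 * 3)
  gain_at <- function(f) {
    y <- bandpass_emg(emg_trace(sin(2 * pi * f * t), fs))$samples
    (max(y[win]) - min(y[win])) / 2
  }
  g1k <- gain_at(1000)
  expect_gt(g1k, 0.9); expect_lt(g1k, 1.1)
  expect_gt(g1k / gain_at(10), 20)
  expect_error(bandpass_emg(emg_trace(rnorm(fs), fs), high_hz = 11000),
               "Nyquist")
})

test_that("integrate_emg is a rectifying leaky integrator", {
  z <- integrate_emg(emg_trace(numeric(5000), fs))
  expect_true(all(z == 0))
  step <- emg_trace(c(numeric(100), rep(-1, 6000)), fs) # rectification flips sign
  y <- integrate_emg(step, tau_s = 0.1)
  expect_true(all(y >= 0))
  i63 <- which(y >= 1 - exp(-1))[1L] - 100L
  expect_lte(abs(i63 - 0.1 * fs), 1)
  expect_error(integrate_emg(step, tau_s = 0), "positive")
})

test_that("reflex metrics recover latency, duration and amplitude", {
  for (lat in c(0.002, 0.005, 0.008, 0.015)) {
    g <- generate_emg(latency_s = lat, peak_to_peak_mv = 1.0,
                      stim_onsets_s = 0.5)
    m <- suppressWarnings(reflex_metrics(g$trace, baseline_window_s = c(0, 0.4)))
    expect_true(m$detected)
    expect_lte(abs(m$latency_s - lat) * fs, 1 + 1e-9)
    expect_lte(abs(m$peak_to_peak_mv - 1.0), 0.05)
    expect_lte(abs(m$duration_s - g$truth$burst_duration_s), 0.002)
  }
})

test_that("absent bursts are reported undetected, stimuli indexed", {
  g <- generate_emg(stim_onsets_s = c(0.5, 1.5), noise_sd_mv = 0.01,
                    peak_to_peak_mv = 0, seed = 2)
  m <- reflex_metrics(g$trace, baseline_window_s = c(0, 0.4), k_sd = 5)
  expect_equal(nrow(m), 2L)
  expect_false(any(m$detected))
  g2 <- generate_emg(stim_onsets_s = c(0.5, 1.5), noise_sd_mv = 0.005, seed = 3)
  m2 <- reflex_metrics(g2$trace, baseline_window_s = c(0, 0.4))
  expect_equal(m2$stimulus, 1:2)
  expect_true(all(m2$detected))
  expect_lt(max(abs(m2$peak_to_peak_mv - 0.83)), 0.05 * 0.83)
})

test_that("peak-to-peak is invariant to a DC offset through the band-pass", {
  g <- generate_emg(stim_onsets_s = 0.5, noise_sd_mv = 0.005, seed = 4)
  raw <- g$trace
  shifted <- emg_trace(raw$samples + 2.5, fs, raw$stim_onsets_s)
  y1 <- bandpass_emg(raw)$samples
  y2 <- bandpass_emg(shifted)$samples
  win <- round(0.5 * fs):round(0.55 * fs) # burst window
  expect_equal(max(y1[win]) - min(y1[win]), max(y2[win]) - min(y2[win]),
               tolerance = 1e-6)
})

test_that("trace validation enforces rate and onset bounds", {
  expect_error(emg_trace(rnorm(100), 1000), ">= 6000")
  expect_error(emg_trace(rnorm(100), 20000, stim_onsets_s = 10), "outside")
  expect_error(generate_emg(sample_rate_hz = 100), ">= 6000")
})

test_that("jaw deflection recovers the programmed amplitude", {
  j <- generate_jaw_track(deflection_um = 305)
  d <- jaw_deflection(j$track)
  expect_equal(nrow(d$per_pulse), 10L)
  expect_true(all(d$per_pulse$valid))
  expect_true(all(abs(d$per_pulse$deflection_um - 305) <= 1))
  expect_equal(mean(d$per_pulse$deflection_um), 305, tolerance = 1e-9)
  # null deflection with jitter stays below 3x the noise bound
  j0 <- generate_jaw_track(deflection_um = 0, noise_sd_px = 0.5, seed = 8)
  d0 <- jaw_deflection(j0$track)
  expect_lt(max(abs(d0$per_pulse$deflection_um)), 3 * 0.5 / 0.5 * 2)
})

test_that("deflection is invariant to a rigid common offset per frame", {
  j <- generate_jaw_track(deflection_um = 150, seed = 5)
  fr <- j$track$frames
  set.seed(6)
  dx <- rnorm(nrow(fr), sd = 4); dy <- rnorm(nrow(fr), sd = 4)
  fr2 <- within(fr, { x_top <- x_top + dx; x_bottom <- x_bottom + dx
                      y_top <- y_top + dy; y_bottom <- y_bottom + dy })
  tr2 <- keypoint_track(fr2, j$track$video_rate_hz, j$track$px_per_um,
                        j$track$trigger_rate_hz, j$track$pulse_onsets_s)
  expect_equal(jaw_deflection(tr2)$per_pulse$deflection_um,
               jaw_deflection(j$track)$per_pulse$deflection_um,
               tolerance = 1e-9)
})

test_that("frame-to-trigger alignment is sub-millisecond", {
  j <- generate_jaw_track(seed = 9)
  d <- jaw_deflection(j$track)
  true_t <- (j$track$frames$frame - min(j$track$frames$frame)) / 170
  expect_lte(max(abs(d$distance$time_s - true_t)), 0.05e-3 + 1e-12)
})

test_that("missing keypoints invalidate only the affected pulse", {
  j <- generate_jaw_track(deflection_um = 100, pulse_onsets_s = c(2, 4), seed = 2)
  fr <- j$track$frames
  hit <- which(abs(fr$frame / 170 - 2.3) < 0.02)
  fr$x_top[hit] <- NA
  tr <- keypoint_track(fr, 170, j$track$px_per_um, 10000, c(2, 4))
  d <- jaw_deflection(tr)
  expect_false(d$per_pulse$valid[1L])
  expect_true(d$per_pulse$valid[2L])
})
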