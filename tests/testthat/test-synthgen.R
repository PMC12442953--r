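short_stim <- stimulus_train("electrical", c(1, 2.67, 4.33), 0.2, c(1L, 2L, 3L))

test_that("every generator is bit-deterministic under a fixed seed", {
  s <- synth_movie_spec(n_frames = 40, n_cells = 6, seed = 42,
                        motion_model = "translation")
  expect_identical(generate_movie(s, short_stim)$movie$frames,
                   generate_movie(s, short_stim)$movie$frames)
  expect_identical(generate_ish_pair(seed = 42)$moving,
                   generate_ish_pair(seed = 42)$moving)
  expect_identical(generate_emg(seed = 42, noise_sd_mv = 0.01)$trace$samples,
                   generate_emg(seed = 42, noise_sd_mv = 0.01)$trace$samples)
  expect_identical(generate_jaw_track(seed = 42, noise_sd_px = 0.3)$track$frames,
                   generate_jaw_track(seed = 42, noise_sd_px = 0.3)$track$frames)
  expect_identical(generate_immune_image(seed = 42, noise_sd = 2)$signal,
                   generate_immune_image(seed = 42, noise_sd = 2)$signal)
})

test_that("an empty noiseless scene is constant across frames", {
  s <- synth_movie_spec(n_frames = 10, n_cells = 0, noise_sd = 0,
                        neuropil_amplitude = 0, motion_model = "none",
                        responder_fraction = 0)
  gen <- generate_movie(s, stimulus_train("electrical", 0.5))
  f1 <- gen$movie$frames[, , 1L]
  expect_true(all(f1 == f1[1L, 1L]))
  for (t in 2:10) expect_identical(gen$movie$frames[, , t], f1)
})

test_that("invalid specifications are rejected", {
  expect_error(synth_movie_spec(responder_fraction = 1.5), "responder_fraction")
  expect_error(synth_movie_spec(height_px = 0), "positive")
  expect_error(synth_movie_spec(cell_diameter_um_range = c(-1, 5)), "positive")
  expect_error(generate_movie(synth_movie_spec(n_frames = 10), electrical_train()),
               "past the recording")
  expect_error(generate_ish_pair(n_guideposts = 5), "at least 6")
  expect_error(generate_ish_pair(warp_magnitude_px = -1), "nonnegative")
  expect_error(generate_jaw_track(video_rate_hz = 0), "positive")
  expect_error(generate_jaw_track(trigger_rate_hz = 100), "at least")
  expect_error(generate_immune_image(n_rois = -1), "nonnegative")
  expect_error(generate_immune_image(roi_intensity = -2), "nonnegative")
})

test_that("scene conservation: frame sums constant outside transients", {
  s <- synth_movie_spec(n_frames = 40, n_cells = 8, noise_sd = 0,
                        motion_model = "none", seed = 3)
  stim <- stimulus_train("electrical", c(4, 5.67, 7.33), 0.2, c(1L, 2L, 3L))
  gen <- generate_movie(s, stim)
  pre <- vapply(1:19, function(t) sum(gen$movie$frames[, , t]), numeric(1))
  expect_lt(diff(range(pre)) / mean(pre), 1e-9)
})

test_that("ground truth is recoverable from the artifacts themselves", {
  # dF amplitude by direct evaluation at the soma
  s <- synth_movie_spec(n_frames = 60, n_cells = 4, responder_fraction = 1,
                        noise_sd = 0, neuropil_amplitude = 0,
                        motion_model = "none", transient_amplitude = 20,
                        seed = 10)
  stim <- stimulus_train("electrical", c(2, 4, 6), 0.2, c(1L, 2L, 3L))
  gen <- generate_movie(s, stim)
  tr <- extract_traces(gen$movie, gen$truth$rois)
  for (i in seq_len(nrow(tr))) {
    peak <- max(tr[i, 11:60]) - mean(tr[i, 1:10])
    expect_lt(abs(peak - 20) / 20, 0.1)
  }
  # warp ground truth at 10 random pixels equals poly + displacement
  pair <- generate_ish_pair(seed = 6)
  set.seed(1)
  px <- cbind(sample(0:159, 10), sample(0:159, 10))
  manual <- map_points_poly(pair$truth$warp$polynomial, px) +
    cbind(pair$truth$warp$displacement[, , 1L][px + 1],
          pair$truth$warp$displacement[, , 2L][px + 1])
  expect_equal(warp_points(pair$truth$warp, px), manual)
  # guidepost pairs are exactly consistent with the true map
  gp <- warp_points(pair$truth$warp, pair$truth$guidepost_fixed)
  expect_lt(max(abs(gp - pair$truth$guidepost_moving)), 1e-8)
  # EMG burst carries the stated amplitude exactly
  g <- generate_emg(peak_to_peak_mv = 0.83, stim_onsets_s = 0.3)
  expect_equal(max(g$trace$samples) - min(g$trace$samples), 0.83)
})

test_that("movies are finite, nonnegative, correctly shaped", {
  s <- synth_movie_spec(n_frames = 20, n_cells = 5, motion_model = "affine",
                        seed = 8)
  gen <- generate_movie(s, stimulus_train("electrical", c(0.5, 1.5, 2.5), 0.2, c(1L, 2L, 3L)))
  expect_equal(dim(gen$movie$frames), c(128, 128, 20))
  expect_true(all(is.finite(gen$movie$frames)))
  expect_true(all(gen$movie$frames >= 0))
  expect_equal(length(gen$truth$motion), 20L)
  expect_equal(nrow(gen$truth$cell_centers), 5L)
})

test_that("responder labels follow the responder fraction", {
  s <- synth_movie_spec(n_frames = 40, n_cells = 10, responder_fraction = 0.4,
                        seed = 12)
  gen <- generate_movie(s, short_stim)
  expect_length(gen$truth$responders, 4L)
  expect_true(all(gen$truth$responder_labels[gen$truth$responders, ]))
  expect_false(any(gen$truth$responder_labels[-gen$truth$responders, ]))
})
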