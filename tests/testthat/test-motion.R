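sc <- blob_scene(seed = 11)
cen <- c((nrow(sc) - 1) / 2, (ncol(sc) - 1) / 2)

test_that("mean_squares matches closed forms and rejects shape mismatch", {
  expect_identical(mean_squares(sc, sc), 0)
  expect_equal(mean_squares(sc, sc + 3), 9)
  expect_equal(mean_squares(matrix(c(0, 2, 1, 3), 2, 2),
                            matrix(c(1, 2, 1, 3), 2, 2)), 0.25)
  expect_error(mean_squares(sc, sc[-1, ]), "shapes differ")
})

test_that("apply_transform honors identity, empty overlap, and inversion", {
  t_id <- affine2d(diag(2), c(0, 0), cen)
  expect_identical(apply_transform(sc, t_id), sc)
  t_off <- affine2d(diag(2), dim(sc), cen)
  expect_true(all(apply_transform(sc, t_off) == 0))
  th <- 5 * pi / 180
  t_rot <- affine2d(matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2),
                    c(1.3, -0.7), cen)
  round_trip <- apply_transform(apply_transform(sc, t_rot), invert_affine(t_rot))
  interior <- 12:(nrow(sc) - 12)
  mad <- mean(abs(round_trip - sc)[interior, interior])
  expect_lt(mad, 0.01 * diff(range(sc)))
})

test_that("compose/invert/map are mutually consistent", {
  a <- affine2d(matrix(c(1.02, 0.01, -0.03, 0.99), 2, 2), c(2, -1), cen)
  b <- affine2d(diag(2) * 0.98, c(-0.5, 3), cen)
  pts <- matrix(runif(10, 10, 80), 5, 2)
  expect_equal(map_points_affine(compose_affine(a, b), pts),
               map_points_affine(b, map_points_affine(a, pts)))
  expect_equal(map_points_affine(compose_affine(a, invert_affine(a)), pts),
               pts, tolerance = 1e-10)
})

test_that("estimate_translation recovers integer and subpixel shifts", {
  # identical images
  t0 <- estimate_translation(sc, sc)
  expect_lt(sqrt(sum(t0$offset^2)), 0.01 + 1e-8)
  for (shift in list(c(3, -2), c(1.5, 0))) {
    # moving(p) = sc(p - shift), so registration must find offset = +shift
    moving <- apply_transform(sc, affine2d(diag(2), -shift, cen))
    est <- estimate_translation(sc, moving)
    oracle <- oracle_int_shift(sc, moving, 5)
    expect_lt(sqrt(sum((est$offset - shift)^2)), 0.5)
    expect_lt(sqrt(sum((est$offset - oracle)^2)), 1.0)
  }
})

test_that("constant images yield a flagged identity translation", {
  flat <- matrix(5, 32, 32)
  expect_warning(tr <- estimate_translation(flat, flat), "constant")
  expect_true(is_identity_affine(tr))
  expect_false(attr(tr, "converged"))
})

test_that("refine_affine recovers rotation and scale, never worsens metric", {
  t_id <- refine_affine(sc, sc)
  expect_lt(max(abs(t_id$linear - diag(2))), 1e-3)
  th <- 2 * pi / 180
  rot <- affine2d(matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2),
                  c(0, 0), cen)
  moving <- apply_transform(sc, invert_affine(rot))
  est <- refine_affine(sc, moving)
  ang <- asin(pmin(1, abs(est$linear[1, 2] - est$linear[2, 1]) / 2)) * 180 / pi
  expect_lt(abs(ang - 2), 0.25)
  expect_lte(attr(est, "final_metric"), attr(est, "initial_metric"))

  scl <- affine2d(diag(2) * 1.03, c(0, 0), cen)
  moving2 <- apply_transform(sc, invert_affine(scl))
  est2 <- refine_affine(sc, moving2)
  expect_lt(abs(sqrt(abs(det(est2$linear))) - 1.03), 0.01)
})

test_that("register_stack leaves a motionless movie unchanged", {
  frames <- array(rep(sc, 4), c(dim(sc), 4))
  frames <- frames + array(rnorm(length(frames), sd = 0.3), dim(frames))
  reg <- register_stack(movie_stack(frames))
  for (tf in reg$transforms) {
    expect_lt(max(abs(tf$linear - diag(2))), 2e-3)
    expect_lt(sqrt(sum(tf$offset^2)), 0.15)
  }
  expect_true(all(reg$metrics$post <= reg$metrics$pre + 1e-12))
})

test_that("register_stack recovers known per-frame translations", {
  gen <- generate_movie(
    synth_movie_spec(n_frames = 30, motion_model = "translation",
                     max_shift_px = 8, n_cells = 12, seed = 9),
    stimulus_train("electrical", c(1, 2.5, 4), 0.2, c(1L, 2L, 3L)))
  reg <- register_stack(gen$movie)
  true_shift <- t(vapply(gen$truth$motion, function(m) m$offset, numeric(2)))
  expect_lt(shift_rms_error(true_shift, reg$transforms), 0.5)
  expect_true(all(reg$metrics$post <= reg$metrics$pre + 1e-12))
})

test_that("segment packaging does not change registration", {
  gen <- generate_movie(
    synth_movie_spec(n_frames = 16, motion_model = "translation",
                     n_cells = 10, seed = 4),
    stimulus_train("electrical", c(0.5, 1.5), 0.2, c(1L, 2L)))
  whole <- register_stack(gen$movie, reference = "first")
  # same frames re-packaged as two concatenated segments of one movie
  seg <- movie_stack(gen$movie$frames[, , c(1:8, 9:16)])
  both <- register_stack(seg, reference = "first")
  for (t in seq_len(16))
    expect_equal(both$transforms[[t]]$offset, whole$transforms[[t]]$offset,
                 tolerance = 1e-10)
})

test_that("composition consistency holds for a pre-shifted frame", {
  # frame pre-shifted by S: its transform composes S^-1 with the transform
  # found for the unshifted frame
  noisy <- sc + matrix(rnorm(length(sc), sd = 0.1), nrow(sc))
  base <- estimate_translation(sc, noisy)
  moving <- apply_transform(noisy, affine2d(diag(2), c(2, 1), cen))
  pre <- estimate_translation(sc, moving)
  expect_lt(sqrt(sum((pre$offset - (base$offset - c(2, 1)))^2)), 0.5)
})

test_that("transforms serialize to JSON and back", {
  path <- withr::local_tempfile(fileext = ".json")
  tfs <- list(affine2d(matrix(c(1, 0.01, -0.02, 0.98), 2, 2), c(1.5, -2), cen),
              affine2d(diag(2), c(0, 0), cen))
  write_transforms_json(tfs, path)
  back <- read_transforms_json(path)
  expect_equal(back[[1L]]$linear, tfs[[1L]]$linear)
  expect_equal(back[[1L]]$offset, tfs[[1L]]$offset)
  expect_equal(back[[2L]]$center, cen)
})
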