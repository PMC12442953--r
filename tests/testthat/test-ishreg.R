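test_that("normalize_percentiles maps the stated percentiles to [0, 1]", {
  ramp <- matrix(0:999, 1000, 1)
  nr <- normalize_percentiles(ramp)
  expect_lt(min(nr), 1e-6)
  expect_gt(max(nr), 1 - 1e-6)
  clipped <- mean(nr == 0 | nr == 1)
  expect_lt(abs(clipped - 0.002), 0.002)
  # idempotence: renormalizing changes almost nothing (tail clipping moves
  # the anchor percentiles by ~1e-6 on this 1000-px ramp)
  expect_lt(max(abs(normalize_percentiles(nr) - nr)), 2e-6)
  expect_warning(z <- normalize_percentiles(matrix(3, 5, 5)), "constant")
  expect_true(all(z == 0))
})

test_that("fit_polynomial_warp is exact on consistent points", {
  set.seed(2)
  pts <- cbind(runif(10, 5, 95), runif(10, 5, 95))
  # identity pairs
  idw <- fit_polynomial_warp(control_points(pts[1:6, ], pts[1:6, ]))
  expect_lt(max(abs(idw$coeffs - polywarp_identity()$coeffs)), 1e-9)
  # known quadratic map, 10 noiseless pairs
  coeffs <- matrix(c(2, 1.01, 0.03, 1e-4, -2e-4, 5e-5,
                     -1, -0.02, 0.98, 3e-5, 1e-4, -2e-4), 6, 2)
  truth <- structure(list(coeffs = coeffs, rms_residual_px = 0),
                     class = "polywarp2")
  moving <- map_points_poly(truth, pts)
  fit <- fit_polynomial_warp(control_points(pts, moving))
  expect_lt(max(abs(fit$coeffs - coeffs)), 1e-6)
  # noisy pairs keep a bounded residual
  fitn <- fit_polynomial_warp(control_points(pts, moving + rnorm(20, sd = 0.5)))
  expect_lte(fitn$rms_residual_px, 1.5)
})

test_that("degenerate control-point configurations are rejected", {
  line <- cbind(1:8, 2 * (1:8) + 1) # all on a line (a degenerate conic)
  expect_error(fit_polynomial_warp(control_points(line, line)), "conic")
  expect_error(control_points(cbind(1:5, 1:5), cbind(1:5, 1:5)), "at least 6")
  dup <- rbind(cbind(1:6, 1:6), c(1, 1))
  expect_error(control_points(dup, dup), "duplicated")
})

test_that("warp model composition order is polynomial-then-displacement", {
  set.seed(4)
  disp <- array(rnorm(30 * 30 * 2, sd = 0.5), c(30, 30, 2))
  poly <- structure(list(coeffs = matrix(c(1, 1.01, 0, 0, 0, 0,
                                           -2, 0, 0.99, 0, 0, 0), 6, 2),
                         rms_residual_px = 0), class = "polywarp2")
  model <- warp_model(poly, disp)
  pts <- cbind(c(3, 10, 21), c(4, 15, 27))
  got <- warp_points(model, pts)
  for (i in 1:3) {
    manual <- map_points_poly(poly, pts[i, , drop = FALSE]) +
      c(disp[pts[i, 1] + 1, pts[i, 2] + 1, 1],
        disp[pts[i, 1] + 1, pts[i, 2] + 1, 2])
    expect_equal(got[i, ], as.numeric(manual))
  }
})

test_that("demons on identical images stays near zero displacement", {
  img <- normalize_percentiles(blob_scene(80, 80, 6, seed = 3))
  model <- demons_refine(img, img)
  expect_lt(sqrt(mean(model$displacement^2)), 0.05)
})

test_that("demons recovers a known smooth warp to <= 1 px RMS", {
  pair <- generate_ish_pair(seed = 1)
  poly <- fit_polynomial_warp(control_points(pair$truth$guidepost_fixed,
                                             pair$truth$guidepost_moving))
  model <- demons_refine(pair$fixed, pair$moving[, , 1L], poly)
  probes <- pair$truth$cell_centers[seq_len(20), ]
  err <- warp_points(model, probes) - warp_points(pair$truth$warp, probes)
  expect_lte(sqrt(mean(rowSums(err^2))), 1)
  m <- attr(model, "metrics")$mean_squares
  expect_true(all(diff(m) <= 1e-12))       # non-increasing across levels
  expect_lte(m[length(m)], m[1L])          # never worse than the polynomial
})

test_that("demons never worsens its initialization across seeds", {
  for (s in c(2, 3)) {
    pair <- generate_ish_pair(seed = s, warp_magnitude_px = 2)
    poly <- fit_polynomial_warp(control_points(pair$truth$guidepost_fixed,
                                               pair$truth$guidepost_moving))
    model <- demons_refine(pair$fixed, pair$moving[, , 1L], poly)
    m <- attr(model, "metrics")$mean_squares
    expect_lte(m[length(m)], m[1L])
  }
})

test_that("apply_warp_stack reduces misalignment and preserves structure", {
  pair <- generate_ish_pair(seed = 2)
  poly <- fit_polynomial_warp(control_points(pair$truth$guidepost_fixed,
                                             pair$truth$guidepost_moving))
  model <- demons_refine(pair$fixed, pair$moving[, , 1L], poly)
  aligned <- apply_warp_stack(pair$moving, model)
  expect_equal(dim(aligned), dim(pair$moving))
  fx <- normalize_percentiles(pair$fixed)
  ms_before <- mean_squares(fx, normalize_percentiles(pair$moving[, , 1L]))
  ms_after <- mean_squares(fx, normalize_percentiles(aligned[, , 1L]))
  expect_lte(ms_after, 0.2 * ms_before)
  # identity model leaves a stack untouched
  idm <- warp_model(polywarp_identity(), shape = dim(pair$fixed))
  expect_equal(apply_warp_stack(pair$moving, idm), pair$moving)
})

test_that("transfer_rois maps masks with label identity preserved", {
  m <- matrix(FALSE, 40, 40); m[15:20, 10:16] <- TRUE
  rois <- roi_set(list(m), c(40, 40), ids = "cellA")
  idm <- warp_model(polywarp_identity(), shape = c(40, 40))
  expect_identical(transfer_rois(rois, idm, "moving")$rois[[1L]]$mask, m)
  expect_identical(transfer_rois(rois, idm, "fixed"), rois)
  # pure translation by (4, 0)
  tr <- structure(list(coeffs = matrix(c(4, 1, 0, 0, 0, 0,
                                         0, 0, 1, 0, 0, 0), 6, 2),
                       rms_residual_px = 0), class = "polywarp2")
  tm <- warp_model(tr, shape = c(40, 40))
  moved <- transfer_rois(rois, tm, "moving")
  expect_equal(moved$rois[[1L]]$id, "cellA")
  cen0 <- colMeans(which(m, arr.ind = TRUE))
  cen1 <- colMeans(which(moved$rois[[1L]]$mask, arr.ind = TRUE))
  expect_lt(max(abs(cen1 - cen0 - c(4, 0))), 0.5)
  # transferred area tracks the true warp's local Jacobian ...
  pair <- generate_ish_pair(seed = 5)
  moved2 <- transfer_rois(pair$truth$rois, pair$truth$warp, "moving")
  a0 <- vapply(pair$truth$rois$rois, function(r) sum(r$mask), numeric(1))
  a1 <- vapply(moved2$rois, function(r) sum(r$mask), numeric(1))
  jac <- vapply(seq_len(nrow(pair$truth$cell_centers)), function(i) {
    p <- pair$truth$cell_centers[i, ]
    h <- 0.5
    dr <- (warp_points(pair$truth$warp, rbind(p + c(h, 0))) -
             warp_points(pair$truth$warp, rbind(p - c(h, 0)))) / (2 * h)
    dc <- (warp_points(pair$truth$warp, rbind(p + c(0, h))) -
             warp_points(pair$truth$warp, rbind(p - c(0, h)))) / (2 * h)
    abs(dr[1] * dc[2] - dr[2] * dc[1])
  }, numeric(1))
  # the forward splat dilates each mask by a sub-pixel boundary band, so
  # allow that on top of the Jacobian prediction
  expect_true(all(abs(a1 / a0 - jac) / jac <= 0.2))
  # ... and stays within 15% absolute under a near-unity-Jacobian warp
  gentle <- generate_ish_pair(seed = 5, warp_magnitude_px = 1)
  moved3 <- transfer_rois(gentle$truth$rois, gentle$truth$warp, "moving")
  g0 <- vapply(gentle$truth$rois$rois, function(r) sum(r$mask), numeric(1))
  g1 <- vapply(moved3$rois, function(r) sum(r$mask), numeric(1))
  expect_true(all(abs(g1 - g0) / g0 <= 0.15))
})

test_that("control points serialize to the pairs JSON schema", {
  path <- withr::local_tempfile(fileext = ".json")
  pts <- control_points(cbind(1:6, 6:1), cbind(2:7, 7:2))
  write_control_points(pts, path)
  back <- read_control_points(path)
  expect_equal(back$fixed, pts$fixed)
  expect_equal(back$moving, pts$moving)
})

test_that("efficiency_specificity implements the two percentages", {
  all_pos <- efficiency_specificity(rep(TRUE, 10), rep(TRUE, 10))
  expect_equal(all_pos, list(efficiency = 100, specificity = 100))
  half <- efficiency_specificity(c(rep(TRUE, 50), rep(FALSE, 50)),
                                 c(rep(TRUE, 45), rep(FALSE, 55)))
  expect_equal(half, list(efficiency = 50, specificity = 90))
  expect_message(none <- efficiency_specificity(rep(FALSE, 5), rep(TRUE, 5)),
                 "undefined")
  expect_equal(none$efficiency, 0)
  expect_true(is.na(none$specificity))
})
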