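test_that("classify_intradental matches brute force over all round patterns", {
  for (R in 2:4) {
    patterns <- expand.grid(rep(list(c(FALSE, TRUE)), R))
    for (i in seq_len(nrow(patterns))) {
      p <- as.logical(patterns[i, ])
      expect_identical(classify_intradental(p), sum(p) >= 2)
    }
  }
  # the three-round rule admits exactly 4 of the 8 patterns
  p3 <- expand.grid(rep(list(c(FALSE, TRUE)), 3))
  expect_equal(sum(apply(p3, 1, function(p) classify_intradental(as.logical(p)))), 4)
  expect_true(classify_intradental(c(TRUE, TRUE), k_required = 2))
  expect_false(classify_intradental(c(FALSE, FALSE, FALSE)))
})

make_trace <- function(onsets, amp, n = 300, rate = 5, decay = 0.4,
                       noise = 0, seed = 1, transient_onsets = onsets) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / rate
  tr <- numeric(n)
  for (on in transient_onsets) tr <- tr + amp * exp(-pmax(t - on, 0) / decay) * (t >= on)
  tr + rnorm(n, sd = noise)
}

stim1 <- stim_round(electrical_train(), 1)

test_that("detect_round_response follows stimulus entrainment", {
  # baseline noise only, no stimulus-locked signal
  quiet <- c(rnorm(40), numeric(260))
  expect_false(detect_round_response(quiet, stim1, response_criterion(threshold_sd = 3)))
  # clear responder (amplitude 20, sigma 1)
  resp <- make_trace(stim1$pulse_onsets_s, 20, noise = 1)
  expect_true(detect_round_response(resp, stim1))
  # anti-phase transients midway between pulses stay sub-threshold
  anti <- make_trace(stim1$pulse_onsets_s, 20, noise = 0.5,
                     transient_onsets = stim1$pulse_onsets_s + 1 / 0.6 / 2)
  expect_false(detect_round_response(
    anti, stim1, response_criterion(response_window_s = 0.8)))
})

test_that("flat baselines warn and use an epsilon SD", {
  tr <- make_trace(stim1$pulse_onsets_s, 20, noise = 0)
  expect_warning(out <- detect_round_response(tr, stim1), "flat baseline")
  expect_true(out)
})

test_that("detect_stimulus_response enforces the persistence rule", {
  expect_false(detect_stimulus_response(c(rnorm(40), numeric(160)), c(8, 20)))
  spike <- numeric(200); spike[60] <- 50
  spike[1:40] <- rnorm(40)
  expect_false(detect_stimulus_response(spike, c(8, 20),
                                        response_criterion(min_consecutive_frames = 2)))
  cutresp <- make_trace(10, 20, n = 200, noise = 1)
  expect_true(detect_stimulus_response(cutresp, c(8, 20)))
})

test_that("raising the threshold never creates responders", {
  for (seed in 1:5) {
    tr <- make_trace(stim1$pulse_onsets_s, runif(1, 0, 10), noise = 1, seed = seed)
    prev <- TRUE
    for (k in c(1, 2, 3, 5, 8, 12)) {
      cur <- detect_round_response(tr, stim1, response_criterion(threshold_sd = k))
      expect_false(!prev && cur)
      prev <- cur
    }
  }
})

test_that("responder classification is accurate on 200 synthetic cells", {
  stim <- electrical_train()
  n <- 200
  truth <- seq_len(n) <= 80
  rr <- matrix(FALSE, n, 3)
  for (i in seq_len(n)) {
    tr <- make_trace(stim$pulse_onsets_s, if (truth[i]) 10 else 0,
                     noise = 1, seed = 1000 + i)
    rr[i, ] <- vapply(1:3, function(r)
      detect_round_response(tr, stim_round(stim, r)), logical(1))
  }
  called <- apply(rr, 1, classify_intradental)
  expect_gte(mean(called[truth]), 0.95)        # sensitivity
  expect_gte(mean(!called[!truth]), 0.95)      # specificity
})

test_that("pool_proportions reproduces printed worked examples", {
  tb <- function(n, k, modality) responder_table(
    paste0("c", seq_len(n)), matrix(TRUE, n, 3),
    stimulus_responses = setNames(list(seq_len(n) <= k), modality))
  expect_equal(pool_proportions(tb(205, 98, "friction"), "friction"),
               list(numerator = 98L, denominator = 205L, percent = 48))
  expect_equal(pool_proportions(tb(27, 22, "cutting"), "cutting", digits = 1)$percent,
               81.4)
  expect_equal(pool_proportions(tb(50, 0, "force"), "force")$percent, 0)
  # pooling across tables sums both margins
  two <- pool_proportions(list(tb(100, 40, "friction"), tb(105, 58, "friction")),
                          "friction")
  expect_equal(two$numerator, 98L)
  expect_equal(two$denominator, 205L)
  # only intradental cells enter the denominator
  mixed <- responder_table(paste0("m", 1:4),
                           rbind(c(TRUE, TRUE, TRUE), c(TRUE, FALSE, FALSE),
                                 c(FALSE, TRUE, TRUE), c(TRUE, TRUE, FALSE)),
                           stimulus_responses = list(cold = c(TRUE, TRUE, FALSE, TRUE)))
  pooled <- pool_proportions(mixed, "cold")
  expect_equal(pooled$denominator, 3L)
  expect_equal(pooled$numerator, 2L)
  empty <- responder_table("x", matrix(c(FALSE, FALSE, FALSE), 1),
                           stimulus_responses = list(cold = TRUE))
  expect_error(pool_proportions(empty, "cold"), "denominator")
})

test_that("percent bounds always hold", {
  set.seed(3)
  for (i in 1:20) {
    n <- sample(5:300, 1); k <- sample(0:n, 1)
    tbl <- responder_table(paste0("c", seq_len(n)), matrix(TRUE, n, 3),
                           stimulus_responses = list(force = seq_len(n) <= k))
    p <- pool_proportions(tbl, "force")
    expect_gte(p$percent, 0); expect_lte(p$percent, 100)
    expect_lte(p$numerator, p$denominator)
  }
})

test_that("score_expression thresholds against out-of-ROI background", {
  m <- matrix(FALSE, 40, 40); m[10:15, 10:15] <- TRUE
  rois <- roi_set(list(m), c(40, 40))
  flat <- matrix(rnorm(1600, 50, 2), 40, 40)
  expect_false(any(score_expression(flat, rois)))
  pos <- flat; pos[m] <- pos[m] + 100
  expect_true(all(score_expression(pos, rois)))
})

test_that("positivity scoring recovers generator labels after alignment", {
  pair <- generate_ish_pair(seed = 1)
  poly <- fit_polynomial_warp(control_points(pair$truth$guidepost_fixed,
                                             pair$truth$guidepost_moving))
  model <- demons_refine(pair$fixed, pair$moving[, , 1L], poly)
  aligned <- apply_warp_stack(pair$moving, model)
  calls <- score_expression(aligned, pair$truth$rois)
  expect_gte(mean(calls == pair$truth$positive), 0.95)
})
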