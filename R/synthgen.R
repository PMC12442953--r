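# Synthetic inputs with known ground truth. The generators state the
# recording conditions of the study (5 Hz widefield acquisition, 7-52 um
# somata, 0.6 Hz / 200 ms electrical pulse trains, 170 Hz video with a
# 10 kHz trigger) and add nominal noise/amplitude defaults where the source
# reports none; see the methods vignette for the rationale of each default.

#' Specification of a synthetic calcium-imaging movie
#'
#' @param height_px,width_px frame size (default 128 x 128).
#' @param n_frames frames (default 300, i.e. 60 s at 5 Hz).
#' @param frame_rate_hz acquisition rate (default 5 Hz).
#' @param pixel_size_um pixel pitch (default 1.625 um, a 6.5 um sensor
#'   behind a 4x objective).
#' @param n_cells somata rendered (default 18, inside the 12-22 neurons
#'   identified per trial).
#' @param cell_diameter_um_range uniform diameter range (default 7-52 um).
#' @param responder_fraction fraction of cells entrained to the stimulus
#'   (default 0.4).
#' @param transient_amplitude transient peak in dF units (default 20).
#' @param transient_decay_s single-exponential decay constant (default
#'   0.4 s, GCaMP6f-like).
#' @param neuropil_amplitude scale of the diffuse contaminant (default 10).
#' @param motion_model `"none"`, `"translation"`, or `"affine"`.
#' @param noise_sd per-pixel Gaussian noise SD (default 1).
#' @param background constant tissue background level (default 200).
#' @param cell_brightness static soma brightness above background
#'   (default 50).
#' @param max_shift_px clamp on the motion random walk (default 10 px).
#' @param max_rotation_deg clamp on affine rotation (default 3 degrees).
#' @param seed RNG seed; equal seed and spec give bit-identical movies.
#' @return a `synth_movie_spec`.
#' @export
synth_movie_spec <- function(height_px = 128L, width_px = 128L,
                             n_frames = 300L, frame_rate_hz = 5,
                             pixel_size_um = 1.625, n_cells = 18L,
                             cell_diameter_um_range = c(7, 52),
                             responder_fraction = 0.4,
                             transient_amplitude = 20,
                             transient_decay_s = 0.4,
                             neuropil_amplitude = 10,
                             motion_model = c("none", "translation", "affine"),
                             noise_sd = 1, background = 200,
                             cell_brightness = 50, max_shift_px = 10,
                             max_rotation_deg = 3, seed = 1L) {
  motion_model <- match.arg(motion_model)
  if (height_px <= 0 || width_px <= 0 || n_frames < 1)
    stop("dimensions and frame count must be positive")
  if (responder_fraction < 0 || responder_fraction > 1)
    stop("responder_fraction must lie in [0, 1]")
  if (any(cell_diameter_um_range <= 0)) stop("diameters must be positive")
  structure(list(height_px = as.integer(height_px),
                 width_px = as.integer(width_px),
                 n_frames = as.integer(n_frames),
                 frame_rate_hz = frame_rate_hz, pixel_size_um = pixel_size_um,
                 n_cells = as.integer(n_cells),
                 cell_diameter_um_range = cell_diameter_um_range,
                 responder_fraction = responder_fraction,
                 transient_amplitude = transient_amplitude,
                 transient_decay_s = transient_decay_s,
                 neuropil_amplitude = neuropil_amplitude,
                 motion_model = motion_model, noise_sd = noise_sd,
                 background = background, cell_brightness = cell_brightness,
                 max_shift_px = max_shift_px,
                 max_rotation_deg = max_rotation_deg,
                 seed = as.integer(seed)),
            class = "synth_movie_spec")
}

#' Electrical identification pulse train
#'
#' Convenience constructor for the three-round electrical paradigm: square
#' pulses at 0.6 Hz with 200 ms duration (12% duty), grouped into rounds.
#'
#' @param n_rounds rounds (default 3).
#' @param pulses_per_round pulses per round (default 5).
#' @param pulse_rate_hz pulse rate (default 0.6 Hz).
#' @param pulse_duration_s pulse width (default 0.2 s).
#' @param start_s onset of the first pulse (default 8 s, i.e. frame 40 at
#'   5 Hz).
#' @param round_gap_s gap between rounds (default 2 s).
#' @return a [stimulus_train()] with modality `"electrical"`.
#' @export
electrical_train <- function(n_rounds = 3L, pulses_per_round = 5L,
                             pulse_rate_hz = 0.6, pulse_duration_s = 0.2,
                             start_s = 8, round_gap_s = 2) {
  period <- 1 / pulse_rate_hz
  onsets <- numeric(0); rounds <- integer(0)
  t0 <- start_s
  for (r in seq_len(n_rounds)) {
    onsets <- c(onsets, t0 + (seq_len(pulses_per_round) - 1L) * period)
    rounds <- c(rounds, rep(r, pulses_per_round))
    t0 <- t0 + pulses_per_round * period + round_gap_s
  }
  stimulus_train("electrical", onsets, pulse_duration_s, rounds,
                 params = list(voltage_v = c(2, 4), rate_hz = pulse_rate_hz,
                               duty = 0.12, offset_v = c(1, 2)))
}

#' Fit the three-round electrical train into a recording
#'
#' Keeps the 0.6 Hz / 200 ms pulse shape and three rounds, shrinking
#' pulses-per-round (down to 1) so the train ends before `duration_s`.
#'
#' @param duration_s recording length (s).
#' @param start_s first-pulse onset (default 8 s).
#' @return a [stimulus_train()].
#' @export
fit_electrical_train <- function(duration_s, start_s = 8) {
  period <- 1 / 0.6; gap <- 2; rounds <- 3L
  avail <- duration_s - start_s - (rounds - 1L) * gap - 1
  ppr <- max(1L, floor(avail / (rounds * period)))
  tr <- electrical_train(n_rounds = rounds, pulses_per_round = ppr,
                         start_s = start_s, round_gap_s = gap)
  if (max(tr$pulse_onsets_s) >= duration_s)
    stop("recording too short for the three-round electrical train")
  tr
}

render_gaussian_blob <- function(h, w, center, sigma, truncate_sigma = 2) {
  g <- coord_grid(h, w)
  r2 <- (g$r - center[1L])^2 + (g$c - center[2L])^2
  prof <- exp(-r2 / (2 * sigma^2))
  prof[r2 > (truncate_sigma * sigma)^2] <- 0
  prof
}

smooth_random_field <- function(h, w, sigma_px) {
  f <- cpp_gauss_blur(matrix(rnorm(h * w), h, w), sigma_px)
  (f - mean(f)) / sd(f) # spatial mean 0, sd 1: conserves the frame sum
}

clamped_walk <- function(n, step_sd, clamp) {
  x <- cumsum(rnorm(n, sd = step_sd))
  pmin(pmax(x, -clamp), clamp)
}

#' Generate a synthetic calcium-imaging movie with ground truth
#'
#' Responder cells emit one transient per pulse (instant rise at pulse
#' onset, exponential decay), added as a flat top-hat over the somatic mask
#' so the generative ROI-mean amplitude equals `transient_amplitude`. A
#' spatially smooth zero-mean neuropil field, scaled per frame by a slow
#' random walk, is added everywhere; each frame is then warped by its true
#' motion and independent Gaussian noise is added.
#'
#' @param spec a [synth_movie_spec()].
#' @param stim a [stimulus_train()] whose onsets fall inside the recording.
#' @return list with `movie` (a [movie_stack()]) and `truth` (centers,
#'   diameters, [roi_set()], responder labels, motion transforms, amplitudes,
#'   the noiseless trace components).
#' @export
generate_movie <- function(spec, stim = electrical_train()) {
  stopifnot(inherits(spec, "synth_movie_spec"), inherits(stim, "stimulus_train"))
  dur <- spec$n_frames / spec$frame_rate_hz
  if (length(stim$pulse_onsets_s) && max(stim$pulse_onsets_s) >= dur)
    stop("stimulus onsets extend past the recording")
  h <- spec$height_px; w <- spec$width_px; T <- spec$n_frames
  # the scene is rendered on a padded canvas and cropped after warping, so
  # motion brings real tissue (not zeros) into the field of view
  pad <- if (spec$motion_model == "none") 0L else
    ceiling(spec$max_shift_px +
              max(h, w) * sin(spec$max_rotation_deg * pi / 180) + 2)
  hp <- h + 2L * pad; wp <- w + 2L * pad
  with_seed(spec$seed, {
    # somata: centers kept a radius away from the border
    diam_px <- runif(spec$n_cells, spec$cell_diameter_um_range[1L],
                     spec$cell_diameter_um_range[2L]) / spec$pixel_size_um
    diam_px <- sort(diam_px, decreasing = TRUE) # place large somata first
    sigma <- diam_px / 4
    margin <- pmax(2 * sigma, 2) + 2
    # non-overlapping somata (distinct cells): rejection sampling on centers
    centers <- matrix(0, spec$n_cells, 2L)
    radius <- 2 * sigma
    placed <- 0L
    tries <- 0L
    while (placed < spec$n_cells && tries < 60000L) {
      tries <- tries + 1L
      i <- placed + 1L
      cand <- c(runif(1, margin[i], h - 1 - margin[i]),
                runif(1, margin[i], w - 1 - margin[i]))
      ok <- placed == 0L ||
        all(sqrt(rowSums(sweep(centers[seq_len(placed), , drop = FALSE],
                               2L, cand)^2)) >
              radius[i] + radius[seq_len(placed)] + 2)
      if (ok) { centers[i, ] <- cand; placed <- i }
    }
    if (placed < spec$n_cells)
      stop("could not place ", spec$n_cells, " non-overlapping somata; ",
           "reduce n_cells or enlarge the field")
    n_resp <- round(spec$responder_fraction * spec$n_cells)
    responders <- if (spec$n_cells > 0)
      sort(sample.int(spec$n_cells, n_resp)) else integer(0)
    rounds <- sort(unique(stim$round_id))
    resp_labels <- matrix(FALSE, spec$n_cells, max(1L, length(rounds)))
    if (length(responders)) resp_labels[responders, ] <- TRUE

    static <- matrix(spec$background, hp, wp)
    masks <- list(); masks_p <- list()
    for (i in seq_len(spec$n_cells)) {
      prof_p <- render_gaussian_blob(hp, wp, centers[i, ] + pad, sigma[i])
      static <- static + spec$cell_brightness * prof_p
      masks_p[[i]] <- prof_p > 0
      masks[[i]] <- render_gaussian_blob(h, w, centers[i, ], sigma[i]) > 0
    }
    rois <- if (spec$n_cells > 0) roi_set(masks, c(h, w)) else NULL

    # per-frame transient amplitude per responder (shared kernel)
    t_frames <- (seq_len(T) - 1L) / spec$frame_rate_hz
    kernel_at <- function(t) {
      a <- numeric(length(t))
      for (on in stim$pulse_onsets_s) {
        active <- t >= on
        a[active] <- a[active] +
          exp(-(t[active] - on) / spec$transient_decay_s)
      }
      a
    }
    amp_t <- spec$transient_amplitude * kernel_at(t_frames)

    np_field <- smooth_random_field(hp, wp, 30)
    np_scale <- clamped_walk(T, 0.05, 1)

    motion <- vector("list", T)
    cen <- c((h - 1) / 2, (w - 1) / 2)
    if (spec$motion_model == "none") {
      for (t in seq_len(T)) motion[[t]] <- affine2d(diag(2), c(0, 0), cen)
    } else {
      dr <- clamped_walk(T, 0.5, spec$max_shift_px)
      dc <- clamped_walk(T, 0.5, spec$max_shift_px)
      th <- if (spec$motion_model == "affine")
        clamped_walk(T, 0.1, spec$max_rotation_deg) * pi / 180 else rep(0, T)
      for (t in seq_len(T)) {
        R <- matrix(c(cos(th[t]), -sin(th[t]), sin(th[t]), cos(th[t])), 2L, 2L)
        motion[[t]] <- affine2d(R, c(dr[t], dc[t]), cen)
      }
    }

    frames <- array(0, c(h, w, T))
    resp_union <- matrix(0, hp, wp)
    for (i in responders) resp_union <- resp_union + masks_p[[i]]
    noise <- if (spec$noise_sd > 0) rnorm(h * w * T, sd = spec$noise_sd) else NULL
    cen_p <- c((hp - 1) / 2, (wp - 1) / 2)
    rows <- (pad + 1L):(pad + h); cols <- (pad + 1L):(pad + w)
    for (t in seq_len(T)) {
      fr <- static + spec$neuropil_amplitude * np_scale[t] * np_field
      if (amp_t[t] > 0 && length(responders))
        fr <- fr + amp_t[t] * resp_union
      if (!is_identity_affine(motion[[t]]))
        fr <- apply_transform(fr, affine2d(motion[[t]]$linear,
                                           motion[[t]]$offset, cen_p))
      fr <- fr[rows, cols]
      if (!is.null(noise))
        fr <- fr + matrix(noise[((t - 1) * h * w + 1):(t * h * w)], h, w)
      frames[, , t] <- pmax(fr, 0)
    }
    movie <- movie_stack(frames, spec$frame_rate_hz, spec$pixel_size_um)
    truth <- list(cell_centers = centers, diameters_px = diam_px,
                  diameters_um = diam_px * spec$pixel_size_um,
                  rois = rois, responders = responders,
                  responder_labels = resp_labels, motion = motion,
                  transient_amplitudes = ifelse(seq_len(spec$n_cells) %in%
                                                  responders,
                                                spec$transient_amplitude, 0),
                  amp_t = amp_t, neuropil_field = np_field,
                  neuropil_scale = np_scale, stim = stim, seed = spec$seed)
    list(movie = movie, truth = truth)
  })
}

#' Generate a fixed/moving ISH image pair with a known warp
#'
#' The moving multichannel stack renders guidepost and non-guidepost cells
#' plus a smooth tissue-texture background; the fixed reference is the
#' guidepost channel observed through a known smooth warp (a second-order
#' polynomial composed with a band-limited random displacement of the
#' stated RMS), so the texture gives the non-rigid refinement gradient
#' information across the whole field, as real ganglion images do. Channel
#' 1 is the guidepost channel; further channels carry per-cell positivity
#' with probability 1/2. Fixed-frame guidepost coordinates are recovered by
#' fixed-point inversion of the true map and exported exactly.
#'
#' @param height_px,width_px image size (default 160 x 160).
#' @param n_guideposts guidepost cells (>= 6; default 10, matching the 8-10
#'   control-point pairs marked in practice).
#' @param n_channels moving-stack channels (default 4).
#' @param warp_magnitude_px RMS of the non-polynomial displacement
#'   (default 3).
#' @param warp_smoothness_px Gaussian correlation length of the random
#'   displacement (default 20 px).
#' @param seed RNG seed.
#' @return list with `fixed`, `moving` (H x W x C array), and `truth`
#'   (warp model, guidepost coordinates in both frames, positivity labels,
#'   fixed-grid [roi_set()]).
#' @export
generate_ish_pair <- function(height_px = 160L, width_px = 160L,
                              n_guideposts = 10L, n_channels = 4L,
                              warp_magnitude_px = 3,
                              warp_smoothness_px = 20, seed = 1L) {
  if (n_guideposts < 6L) stop("need at least 6 guideposts for a quadratic fit")
  if (warp_magnitude_px < 0) stop("warp magnitude must be nonnegative")
  h <- height_px; w <- width_px
  with_seed(seed, {
    margin <- 18
    n_extra <- n_guideposts # additional non-guidepost cells
    n_cells <- n_guideposts + n_extra
    # cell centers live in the MOVING (post hoc ISH) frame; distinct cells
    # do not overlap. Guideposts are stratified across the full surface
    # (control points are marked "distributed across the full surface"),
    # which keeps the quadratic fit from extrapolating wildly at the edges.
    sigma <- runif(n_cells, 3, 5)
    k <- seq_len(n_guideposts)
    u <- (k - 0.5) / n_guideposts + runif(n_guideposts, -0.2, 0.2) / n_guideposts
    v <- ((k * (sqrt(5) - 1) / 2) %% 1) * 0.92 + 0.04 +
      runif(n_guideposts, -0.1, 0.1) / n_guideposts
    gp <- cbind(margin + pmin(pmax(u, 0), 1) * (h - 1 - 2 * margin),
                margin + pmin(pmax(v, 0), 1) * (w - 1 - 2 * margin))
    moving_centers <- matrix(0, n_cells, 2L)
    moving_centers[seq_len(n_guideposts), ] <- gp
    placed <- n_guideposts; tries <- 0L
    while (placed < n_cells && tries < 20000L) {
      tries <- tries + 1L
      i <- placed + 1L
      cand <- c(runif(1, margin, h - 1 - margin),
                runif(1, margin, w - 1 - margin))
      sep <- 2 * (sigma[i] + sigma[seq_len(placed)]) + 2
      ok <- all(sqrt(rowSums(sweep(moving_centers[seq_len(placed), ,
                                                  drop = FALSE], 2L, cand)^2)) > sep)
      if (ok) { moving_centers[i, ] <- cand; placed <- i }
    }
    if (placed < n_cells)
      stop("could not place ", n_cells, " non-overlapping cells")

    # true mapping fixed -> moving: mild quadratic polynomial +
    # band-limited displacement
    cen <- c((h - 1) / 2, (w - 1) / 2)
    th <- runif(1, -2, 2) * pi / 180
    sc <- runif(1, 0.98, 1.02)
    A <- sc * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L)
    off <- runif(2, -4, 4)
    q2 <- matrix(runif(6, -1, 1) * 2e-4, 3L, 2L) # quadratic terms
    coeffs <- matrix(0, 6L, 2L)
    # affine part expressed about the center: p -> A (p - cen) + cen + off
    coeffs[1L, ] <- cen + off - as.numeric(A %*% cen)
    coeffs[2L, ] <- A[, 1L]; coeffs[3L, ] <- A[, 2L]
    coeffs[4:6, ] <- q2
    poly <- structure(list(coeffs = coeffs, rms_residual_px = 0),
                      class = "polywarp2")
    if (warp_magnitude_px > 0) {
      fr <- smooth_random_field(h, w, warp_smoothness_px)
      fc <- smooth_random_field(h, w, warp_smoothness_px)
      rms <- sqrt(mean(fr^2 + fc^2))
      disp <- array(c(fr, fc) * (warp_magnitude_px / rms), c(h, w, 2L))
    } else disp <- array(0, c(h, w, 2L))
    truth_warp <- warp_model(poly, disp)

    # fixed-frame cell coordinates: invert the near-identity map by
    # fixed-point iteration p <- p - (map(p) - q)
    centers <- moving_centers
    for (it in 1:40)
      centers <- centers - (warp_points(truth_warp, centers) - moving_centers)
    # re-export the moving coordinates exactly consistent with the map
    moving_centers <- warp_points(truth_warp, centers)
    is_guidepost <- seq_len(n_cells) <= n_guideposts
    positive <- matrix(runif(n_cells * n_channels) < 0.5, n_cells, n_channels)
    positive[, 1L] <- is_guidepost # channel 1 = guidepost channel

    texture <- 60 * smooth_random_field(h, w, 6) + 40
    render <- function(which_cells, amp = 600) {
      img <- pmax(texture, 0)
      for (i in which_cells)
        img <- img + amp * render_gaussian_blob(h, w, moving_centers[i, ],
                                                sigma[i])
      img
    }
    # fixed = guidepost scene observed through the true map
    maps <- warp_coord_maps(truth_warp)
    fixed <- cpp_warp_map(render(which(is_guidepost)), maps$r, maps$c)
    moving <- array(0, c(h, w, n_channels))
    for (k in seq_len(n_channels))
      moving[, , k] <- render(which(positive[, k]))

    masks <- lapply(seq_len(n_cells), function(i)
      render_gaussian_blob(h, w, centers[i, ], sigma[i]) > 0)
    rois <- roi_set(masks, c(h, w))
    list(fixed = fixed, moving = moving,
         truth = list(warp = truth_warp,
                      guidepost_fixed = centers[is_guidepost, , drop = FALSE],
                      guidepost_moving =
                        moving_centers[is_guidepost, , drop = FALSE],
                      cell_centers = centers, positive = positive,
                      rois = rois, seed = seed))
  })
}

#' Generate a synthetic EMG trace with reflex bursts
#'
#' Each stimulus is followed, after `latency_s`, by a band-limited burst (a
#' half-sine-windowed tone at the geometric center of the 100-3000 Hz band)
#' scaled to the exact peak-to-peak amplitude, plus Gaussian noise. The
#' burst is band-limited by construction, i.e. already in the filtered
#' domain consumed by [reflex_metrics()].
#'
#' @param sample_rate_hz sampling rate (>= 6000; default 20 kHz).
#' @param stim_onsets_s stimulus onsets (s).
#' @param latency_s reflex latency (default 0.008 s).
#' @param burst_duration_s burst length (default 0.02 s).
#' @param peak_to_peak_mv burst amplitude (default 0.83 mV, the reported
#'   digastric response).
#' @param noise_sd_mv Gaussian noise SD (default 0).
#' @param seed RNG seed.
#' @return list with `trace` (an [emg_trace()]) and `truth`.
#' @export
generate_emg <- function(sample_rate_hz = 20000, stim_onsets_s = c(0.5),
                         latency_s = 0.008, burst_duration_s = 0.02,
                         peak_to_peak_mv = 0.83, noise_sd_mv = 0, seed = 1L) {
  if (sample_rate_hz < 6000) stop("sample_rate_hz must be >= 6000")
  if (latency_s < 0) stop("latency must be nonnegative")
  dur <- if (length(stim_onsets_s))
    max(stim_onsets_s) + latency_s + burst_duration_s + 0.5 else 1
  n <- ceiling(dur * sample_rate_hz)
  with_seed(seed, {
    x <- numeric(n)
    f_carrier <- sqrt(100 * 3000) # geometric band center: unit filter gain
    nb <- round(burst_duration_s * sample_rate_hz)
    if (nb >= 2 && length(stim_onsets_s)) {
      u <- (seq_len(nb) - 1L) / nb
      burst <- sin(pi * u) * sin(2 * pi * f_carrier * u * burst_duration_s)
      burst <- burst * (peak_to_peak_mv / (max(burst) - min(burst)))
      for (on in stim_onsets_s) {
        i0 <- round((on + latency_s) * sample_rate_hz) + 1L
        idx <- i0:min(n, i0 + nb - 1L)
        x[idx] <- x[idx] + burst[seq_along(idx)]
      }
    }
    if (noise_sd_mv > 0) x <- x + rnorm(n, sd = noise_sd_mv)
    trace <- emg_trace(x, sample_rate_hz, stim_onsets_s, "digastric")
    list(trace = trace,
         truth = list(latency_s = latency_s, peak_to_peak_mv = peak_to_peak_mv,
                      burst_duration_s = burst_duration_s, seed = seed))
  })
}

#' Generate a synthetic two-keypoint jaw track
#'
#' The incisor separation rises by `deflection_um` (trapezoid with a 10%
#' ramp, so the plateau carries the exact programmed deflection) during each
#' pulse window; coordinates carry optional Gaussian jitter. Frame times are
#' defined on the video clock and aligned downstream to the trigger clock.
#'
#' @param video_rate_hz video rate (default 170 Hz).
#' @param trigger_rate_hz trigger sampling rate (default 10 kHz).
#' @param pulse_onsets_s light-pulse onsets (default a 10-pulse 0.5 Hz
#'   train starting at 2 s).
#' @param deflection_um programmed deflection (default 305 um, the reported
#'   average).
#' @param deflection_duration_s deflection duration (default 1 s, the pulse
#'   length).
#' @param px_per_um pixel scale (default 0.5 px/um).
#' @param noise_sd_px keypoint jitter SD (default 0).
#' @param seed RNG seed.
#' @return list with `track` (a [keypoint_track()]) and `truth`.
#' @export
generate_jaw_track <- function(video_rate_hz = 170, trigger_rate_hz = 10000,
                               pulse_onsets_s = 2 + 2 * (0:9),
                               deflection_um = 305,
                               deflection_duration_s = 1, px_per_um = 0.5,
                               noise_sd_px = 0, seed = 1L) {
  if (video_rate_hz <= 0 || trigger_rate_hz <= 0) stop("rates must be positive")
  if (trigger_rate_hz < video_rate_hz)
    stop("trigger rate must be at least the video rate")
  dur <- if (length(pulse_onsets_s))
    max(pulse_onsets_s) + deflection_duration_s + 1 else 2
  nf <- ceiling(dur * video_rate_hz)
  with_seed(seed, {
    t <- (seq_len(nf) - 1L) / video_rate_hz
    shape <- numeric(nf)
    for (on in pulse_onsets_s) {
      u <- (t - on) / deflection_duration_s
      tr <- pmin(1, pmin(u / 0.1, (1 - u) / 0.1))
      tr[u < 0 | u > 1] <- 0
      shape <- pmax(shape, pmax(tr, 0))
    }
    base_sep_px <- 2000 * px_per_um
    sep_px <- base_sep_px + shape * deflection_um * px_per_um
    frames <- data.frame(frame = seq_len(nf) - 1L,
                         x_top = rep(100, nf), y_top = rep(100, nf),
                         x_bottom = rep(100, nf), y_bottom = 100 + sep_px)
    if (noise_sd_px > 0)
      for (col in c("x_top", "y_top", "x_bottom", "y_bottom"))
        frames[[col]] <- frames[[col]] + rnorm(nf, sd = noise_sd_px)
    track <- keypoint_track(frames, video_rate_hz, px_per_um, trigger_rate_hz,
                            pulse_onsets_s)
    list(track = track,
         truth = list(deflection_um = deflection_um, seed = seed))
  })
}

#' Generate a synthetic two-channel immune-staining image
#'
#' Nuclear channel: bright disc-shaped ROI blobs on a dim background.
#' Signal channel: `roi_intensity` inside the ROIs, `background_intensity`
#' outside.
#'
#' @param height_px,width_px image size (default 256 x 256).
#' @param n_rois disc ROIs (default 5).
#' @param roi_intensity signal level inside ROIs (default 100).
#' @param background_intensity signal level outside (default 10).
#' @param noise_sd optional Gaussian noise SD on both channels (default 0).
#' @param seed RNG seed.
#' @return list with `nuclear`, `signal`, and `truth` (`mask`).
#' @export
generate_immune_image <- function(height_px = 256L, width_px = 256L,
                                  n_rois = 5L, roi_intensity = 100,
                                  background_intensity = 10, noise_sd = 0,
                                  seed = 1L) {
  if (n_rois < 0) stop("n_rois must be nonnegative")
  if (roi_intensity < 0 || background_intensity < 0)
    stop("intensities must be nonnegative")
  h <- height_px; w <- width_px
  with_seed(seed, {
    mask <- matrix(FALSE, h, w)
    radius <- 10
    centers <- matrix(0, 0, 2L)
    tries <- 0L
    while (nrow(centers) < n_rois && tries < 2000L) {
      tries <- tries + 1L
      cand <- c(runif(1, radius + 2, h - 1 - radius - 2),
                runif(1, radius + 2, w - 1 - radius - 2))
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums(sweep(centers, 2L, cand)^2))) > 2.5 * radius)
        centers <- rbind(centers, cand)
    }
    g <- coord_grid(h, w)
    for (i in seq_len(nrow(centers)))
      mask <- mask | ((g$r - centers[i, 1L])^2 + (g$c - centers[i, 2L])^2
                      <= radius^2)
    nuclear <- matrix(10, h, w)
    nuclear[mask] <- 200
    signal <- matrix(background_intensity, h, w)
    signal[mask] <- roi_intensity
    if (noise_sd > 0) {
      nuclear <- nuclear + matrix(rnorm(h * w, sd = noise_sd), h, w)
      signal <- signal + matrix(rnorm(h * w, sd = noise_sd), h, w)
    }
    list(nuclear = nuclear, signal = signal,
         truth = list(mask = mask, centers = centers, radius_px = radius,
                      seed = seed))
  })
}
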