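# EMG reflex quantification and jaw-opening kinematics.

#' EMG trace container
#'
#' @param samples voltage samples (mV).
#' @param sample_rate_hz sampling rate; must be at least 6 kHz (Nyquist for
#'   the 100-3000 Hz band-pass).
#' @param stim_onsets_s stimulus onset times (s), within the trace.
#' @param channel `"digastric"` or `"masseter"`.
#' @return an `emg_trace`.
#' @export
emg_trace <- function(samples, sample_rate_hz, stim_onsets_s = numeric(0),
                      channel = c("digastric", "masseter")) {
  channel <- match.arg(channel)
  samples <- as.numeric(samples)
  if (sample_rate_hz < 6000) stop("sample_rate_hz must be >= 6000")
  dur <- length(samples) / sample_rate_hz
  if (length(stim_onsets_s) && any(stim_onsets_s < 0 | stim_onsets_s > dur))
    stop("stimulus onsets outside the trace")
  structure(list(samples = samples, sample_rate_hz = sample_rate_hz,
                 stim_onsets_s = as.numeric(stim_onsets_s), channel = channel),
            class = "emg_trace")
}

#' @export
print.emg_trace <- function(x, ...) {
  cat(sprintf("emg_trace (%s): %d samples @ %g Hz, %d stimulus onset(s)\n",
              x$channel, length(x$samples), x$sample_rate_hz,
              length(x$stim_onsets_s)))
  invisible(x)
}

#' Zero-phase band-pass filter an EMG trace
#'
#' 4th-order Butterworth with the stated corners, applied forward-backward
#' (zero phase); DC is removed by the band-pass.
#'
#' @param trace an [emg_trace()].
#' @param low_hz,high_hz band corners (defaults 100 and 3000 Hz).
#' @param order filter order (default 4).
#' @return filtered [emg_trace()].
#' @export
bandpass_emg <- function(trace, low_hz = 100, high_hz = 3000, order = 4L) {
  stopifnot(inherits(trace, "emg_trace"))
  if (high_hz >= trace$sample_rate_hz / 2)
    stop("upper corner must be below Nyquist")
  coef <- butter_bandpass(order, low_hz, high_hz, trace$sample_rate_hz)
  out <- trace
  out$samples <- filtfilt_bp(coef$b, coef$a, trace$samples)
  out
}

#' Rectify-and-integrate an EMG trace
#'
#' Full-wave rectification followed by a single-pole leaky integrator with
#' time constant `tau_s` (63% step response at `tau_s`). Output is
#' nonnegative for any input.
#'
#' @param trace a filtered [emg_trace()].
#' @param tau_s integration time constant (default 0.1 s).
#' @return numeric vector of integrated activity.
#' @export
integrate_emg <- function(trace, tau_s = 0.1) {
  stopifnot(inherits(trace, "emg_trace"))
  if (tau_s <= 0) stop("tau_s must be positive")
  alpha <- exp(-1 / (tau_s * trace$sample_rate_hz))
  x <- abs(trace$samples)
  as.numeric(stats::filter((1 - alpha) * x, alpha, method = "recursive"))
}

#' Reflex latency, duration and peak-to-peak amplitude per stimulus
#'
#' Operates on a band-limited trace (apply [bandpass_emg()] first for raw
#' recordings; it is not re-applied internally so that onset timing is not
#' blurred by acausal filtering). For each stimulus: the reflex onset is the
#' first post-stimulus sample where the rectified trace exceeds the baseline
#' mean plus `k_sd` baseline SDs; the end is the last supra-threshold sample
#' before a sub-threshold run of at least `end_gap_s`; duration is end minus
#' onset; peak-to-peak is max minus min of the unrectified trace on
#' `[onset, end]`. No crossing within `search_window_s` marks the stimulus
#' undetected.
#'
#' @param trace a band-passed [emg_trace()] with stimulus onsets.
#' @param baseline_window_s `(start_s, end_s)` window preceding the first
#'   stimulus.
#' @param k_sd onset threshold in baseline SDs (default 3).
#' @param end_gap_s sub-threshold run terminating the burst (default 5 ms).
#' @param search_window_s post-stimulus search horizon (default 100 ms,
#'   covering protective-reflex latencies of 5-15 ms).
#' @return data.frame, one row per stimulus: `stimulus`, `detected`,
#'   `latency_s`, `duration_s`, `peak_to_peak_mv`.
#' @export
reflex_metrics <- function(trace, baseline_window_s, k_sd = 3,
                           end_gap_s = 0.005, search_window_s = 0.1) {
  stopifnot(inherits(trace, "emg_trace"))
  if (!length(trace$stim_onsets_s)) stop("trace carries no stimulus onsets")
  fs <- trace$sample_rate_hz
  if (baseline_window_s[2L] > min(trace$stim_onsets_s))
    stop("baseline window must precede the first stimulus")
  x <- trace$samples
  rect <- abs(x)
  b0 <- max(1L, floor(baseline_window_s[1L] * fs) + 1L)
  b1 <- max(b0, floor(baseline_window_s[2L] * fs))
  mu <- mean(rect[b0:b1])
  sigma <- sd(rect[b0:b1])
  if (is.na(sigma) || sigma == 0) {
    warning("flat baseline; using machine-epsilon SD")
    sigma <- .Machine$double.eps
  }
  thr <- mu + k_sd * sigma
  gap_n <- max(1L, round(end_gap_s * fs))
  out <- lapply(seq_along(trace$stim_onsets_s), function(si) {
    s0 <- round(trace$stim_onsets_s[si] * fs) + 1L
    s1 <- min(length(x), s0 + round(search_window_s * fs))
    above <- which(rect[s0:s1] > thr)
    if (!length(above))
      return(data.frame(stimulus = si, detected = FALSE, latency_s = NA_real_,
                        duration_s = NA_real_, peak_to_peak_mv = NA_real_))
    onset <- s0 + above[1L] - 1L
    # walk forward until a sub-threshold run of >= gap_n samples (or trace end)
    idx <- onset
    last_above <- onset
    run <- 0L
    while (idx < length(x)) {
      idx <- idx + 1L
      if (rect[idx] > thr) { last_above <- idx; run <- 0L }
      else { run <- run + 1L; if (run >= gap_n) break }
    }
    seg <- x[onset:last_above]
    data.frame(stimulus = si, detected = TRUE,
               latency_s = (onset - s0) / fs,
               duration_s = (last_above - onset) / fs,
               peak_to_peak_mv = max(seg) - min(seg))
  })
  do.call(rbind, out)
}

#' Two-keypoint track container (top and bottom incisor)
#'
#' @param frames data.frame with columns `frame`, `x_top`, `y_top`,
#'   `x_bottom`, `y_bottom` (px; NA for missing detections).
#' @param video_rate_hz video frame rate (170 Hz in the study).
#' @param px_per_um pixels per micrometre.
#' @param trigger_rate_hz trigger sampling rate (10 kHz in the study).
#' @param pulse_onsets_s light-pulse onsets on the trigger clock (s).
#' @return a `keypoint_track`.
#' @export
keypoint_track <- function(frames, video_rate_hz = 170, px_per_um = 0.5,
                           trigger_rate_hz = 10000,
                           pulse_onsets_s = numeric(0)) {
  need <- c("frame", "x_top", "y_top", "x_bottom", "y_bottom")
  stopifnot(all(need %in% names(frames)), video_rate_hz > 0, px_per_um > 0,
            trigger_rate_hz >= video_rate_hz)
  structure(list(frames = frames, video_rate_hz = video_rate_hz,
                 px_per_um = px_per_um, trigger_rate_hz = trigger_rate_hz,
                 pulse_onsets_s = as.numeric(pulse_onsets_s)),
            class = "keypoint_track")
}

#' Jaw deflection per light pulse
#'
#' Computes the per-frame Euclidean distance between the incisor keypoints,
#' aligns frame times to the trigger clock by nearest-sample matching, and
#' for each pulse reports the maximum rise of the distance above its
#' pre-pulse baseline, converted to micrometres. Pulses whose window contains
#' missing keypoints are marked invalid.
#'
#' @param track a [keypoint_track()].
#' @param pulse_window_s window after each pulse onset scanned for the
#'   deflection (default 1 s, the pulse duration).
#' @param baseline_window_s pre-pulse window for the baseline distance
#'   (default 0.5 s).
#' @return list with `per_pulse` (data.frame: `pulse`, `valid`,
#'   `deflection_um`) and `distance` (data.frame: `time_s`, `distance_um`).
#' @export
jaw_deflection <- function(track, pulse_window_s = 1.0,
                           baseline_window_s = 0.5) {
  stopifnot(inherits(track, "keypoint_track"))
  fr <- track$frames
  d_px <- sqrt((fr$x_top - fr$x_bottom)^2 + (fr$y_top - fr$y_bottom)^2)
  d_um <- d_px / track$px_per_um
  # frame times quantized to the trigger clock (nearest sample)
  t_raw <- (fr$frame - min(fr$frame)) / track$video_rate_hz
  t_s <- round(t_raw * track$trigger_rate_hz) / track$trigger_rate_hz
  per <- lapply(seq_along(track$pulse_onsets_s), function(pi) {
    t0 <- track$pulse_onsets_s[pi]
    in_bl <- t_s >= t0 - baseline_window_s & t_s < t0
    in_win <- t_s >= t0 & t_s <= t0 + pulse_window_s
    if (!any(in_bl) || !any(in_win) ||
        anyNA(d_um[in_bl]) || anyNA(d_um[in_win]))
      return(data.frame(pulse = pi, valid = FALSE, deflection_um = NA_real_))
    data.frame(pulse = pi, valid = TRUE,
               deflection_um = max(d_um[in_win]) - mean(d_um[in_bl]))
  })
  list(per_pulse = do.call(rbind, per),
       distance = data.frame(time_s = t_s, distance_um = d_um))
}
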