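# Stimulus-locked response detection, the intradental >=2-of-3 rule, pooled
# proportions and ISH positivity scoring.

#' Stimulus train description
#'
#' Pulse onsets grouped into rounds with modality metadata. The electrical
#' identification paradigm delivers 2-4 V square pulses at 0.6 Hz with 12%
#' duty (200 ms pulses) in three independent rounds.
#'
#' @param modality one of `"electrical"`, `"force"`, `"cold"`, `"cutting"`,
#'   `"friction"`, `"vibration"`.
#' @param pulse_onsets_s strictly increasing onset times (s).
#' @param pulse_duration_s pulse duration (s); electrical default 0.2.
#' @param round_id integer round label per pulse (default: all round 1).
#' @param params free-form parameter list (voltage, rate, duty, ...).
#' @return a `stimulus_train`.
#' @export
stimulus_train <- function(modality, pulse_onsets_s, pulse_duration_s = 0.2,
                           round_id = NULL, params = list()) {
  modality <- match.arg(modality, c("electrical", "force", "cold", "cutting",
                                    "friction", "vibration"))
  pulse_onsets_s <- as.numeric(pulse_onsets_s)
  if (length(pulse_onsets_s) && any(diff(pulse_onsets_s) <= 0))
    stop("pulse onsets must be strictly increasing")
  if (pulse_duration_s <= 0) stop("pulse duration must be positive")
  if (is.null(round_id)) round_id <- rep(1L, length(pulse_onsets_s))
  if (length(round_id) != length(pulse_onsets_s))
    stop("every pulse needs a round id")
  structure(list(modality = modality, pulse_onsets_s = pulse_onsets_s,
                 pulse_duration_s = pulse_duration_s,
                 round_id = as.integer(round_id), params = params),
            class = "stimulus_train")
}

#' Restrict a stimulus train to one round
#' @param stim a [stimulus_train()].
#' @param round round id to keep.
#' @return a [stimulus_train()] containing that round's pulses.
#' @export
stim_round <- function(stim, round) {
  keep <- stim$round_id == round
  stimulus_train(stim$modality, stim$pulse_onsets_s[keep],
                 stim$pulse_duration_s, stim$round_id[keep], stim$params)
}

#' Response detection settings
#'
#' @param baseline_window_frames inclusive 0-based frame window for baseline
#'   mean/sd.
#' @param threshold_sd detection threshold in baseline SDs (default 3).
#' @param response_window_s window after each pulse onset scanned for the
#'   entrained response (default 1.0 s).
#' @param min_consecutive_frames persistence rule for non-electrical stimuli
#'   (default 2 frames).
#' @return a `response_criterion`.
#' @export
response_criterion <- function(baseline_window_frames = c(0L, 39L),
                               threshold_sd = 3, response_window_s = 1.0,
                               min_consecutive_frames = 2L) {
  stopifnot(threshold_sd > 0, response_window_s > 0,
            min_consecutive_frames >= 1)
  structure(list(baseline_window_frames = as.integer(baseline_window_frames),
                 threshold_sd = threshold_sd,
                 response_window_s = response_window_s,
                 min_consecutive_frames = as.integer(min_consecutive_frames)),
            class = "response_criterion")
}

baseline_stats <- function(trace, crit) {
  win <- (crit$baseline_window_frames[1L] + 1L):(crit$baseline_window_frames[2L] + 1L)
  if (max(win) > length(trace)) stop("baseline window outside trace")
  bl <- trace[win]
  s <- sd(bl)
  if (is.na(s) || s == 0) {
    warning("flat baseline; using machine-epsilon SD")
    s <- .Machine$double.eps
  }
  list(mu = mean(bl), sigma = s)
}

#' Detect an entrained response to one electrical round
#'
#' Builds the pulse-triggered average of the trace over the round's pulses on
#' `[0, response_window_s]`, after subtracting each segment's immediate
#' pre-pulse level (so slow drifts do not masquerade as entrainment), and
#' reports whether its peak exceeds `threshold_sd` baseline SDs. Pulse-
#' triggered averaging is robust at the 0.6 Hz pulse rate of the
#' identification paradigm.
#'
#' @param trace numeric vector (one cell).
#' @param stim [stimulus_train()] restricted to one electrical round.
#' @param crit a [response_criterion()].
#' @param frame_rate_hz movie frame rate (Hz).
#' @return logical.
#' @export
detect_round_response <- function(trace, stim, crit = response_criterion(),
                                  frame_rate_hz = 5) {
  trace <- as.numeric(trace)
  bs <- baseline_stats(trace, crit)
  nwin <- max(1L, floor(crit$response_window_s * frame_rate_hz))
  segs <- lapply(stim$pulse_onsets_s, function(t0) {
    f0 <- round(t0 * frame_rate_hz) + 1L
    f1 <- f0 + nwin
    if (f1 > length(trace)) return(NULL)
    pre <- trace[max(1L, f0 - 2L):max(1L, f0 - 1L)]
    trace[f0:f1] - mean(pre)
  })
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (!length(segs)) stop("round pulses fall outside the trace")
  pta <- Reduce(`+`, segs) / length(segs)
  max(pta) > crit$threshold_sd * bs$sigma
}

#' Intradental classification rule
#'
#' A cell is intradental when it responded in at least `k_required` of its
#' electrical-stimulation rounds (>= 2 of 3 in the identification paradigm).
#'
#' @param round_responses logical vector, one entry per round.
#' @param k_required minimum number of responding rounds (default 2).
#' @return logical.
#' @export
classify_intradental <- function(round_responses, k_required = 2L) {
  stopifnot(length(round_responses) >= 1L)
  sum(round_responses) >= k_required
}

#' Detect a response inside a known stimulation window
#'
#' The persistence rule for non-periodic stimuli: TRUE when the trace exceeds
#' baseline mean + `threshold_sd` SD for at least `min_consecutive_frames`
#' consecutive frames within the window.
#'
#' @param trace numeric vector.
#' @param window_s `(start_s, end_s)` stimulation window.
#' @param crit a [response_criterion()].
#' @param frame_rate_hz frame rate (Hz).
#' @return logical.
#' @export
detect_stimulus_response <- function(trace, window_s,
                                     crit = response_criterion(),
                                     frame_rate_hz = 5) {
  trace <- as.numeric(trace)
  bs <- baseline_stats(trace, crit)
  f0 <- max(1L, round(window_s[1L] * frame_rate_hz) + 1L)
  f1 <- min(length(trace), round(window_s[2L] * frame_rate_hz) + 1L)
  if (f0 > f1) stop("stimulation window outside trace")
  above <- trace[f0:f1] > bs$mu + crit$threshold_sd * bs$sigma
  r <- rle(above)
  any(r$values & r$lengths >= crit$min_consecutive_frames)
}

#' Responder table
#'
#' One row per cell: electrical round responses, the intradental flag,
#' per-modality response flags and AUCs, and somal diameter.
#'
#' @param cell_id character ids.
#' @param round_responses logical matrix (cells x rounds).
#' @param stimulus_responses named list of logical vectors (per modality).
#' @param auc named list of numeric vectors (per modality), optional.
#' @param diameter_um numeric vector, optional.
#' @param k_required rounds required for intradental status (default 2).
#' @return a `responder_table` (data.frame).
#' @export
responder_table <- function(cell_id, round_responses,
                            stimulus_responses = list(), auc = list(),
                            diameter_um = NULL, k_required = 2L) {
  round_responses <- as.matrix(round_responses)
  n <- length(cell_id)
  stopifnot(nrow(round_responses) == n)
  df <- data.frame(cell_id = as.character(cell_id),
                   stringsAsFactors = FALSE)
  for (r in seq_len(ncol(round_responses)))
    df[[paste0("round", r)]] <- as.logical(round_responses[, r])
  df$is_intradental <- apply(round_responses, 1L, classify_intradental,
                             k_required = k_required)
  for (m in names(stimulus_responses))
    df[[paste0("responds_", m)]] <- as.logical(stimulus_responses[[m]])
  for (m in names(auc)) df[[paste0("auc_", m)]] <- as.numeric(auc[[m]])
  df$diameter_um <- if (is.null(diameter_um)) NA_real_ else as.numeric(diameter_um)
  class(df) <- c("responder_table", "data.frame")
  df
}

#' Pool responder proportions across recordings
#'
#' Denominator: all intradental cells across the tables. Numerator: those
#' whose `responds_<modality>` flag is TRUE. Percent is `100 * num / den`,
#' rounded half away from zero to the nearest integer by default; at
#' `digits = 1` the value is truncated to one decimal (matching the printed
#' convention in which 22/27 reports as 81.4).
#'
#' @param tables a [responder_table()] or list of them.
#' @param modality modality to pool.
#' @param digits 0 (integer percent, default) or 1.
#' @return list with `numerator`, `denominator`, `percent`.
#' @export
pool_proportions <- function(tables, modality, digits = 0L) {
  if (inherits(tables, "responder_table")) tables <- list(tables)
  col <- paste0("responds_", modality)
  num <- den <- 0L
  for (tb in tables) {
    intr <- tb$is_intradental
    den <- den + sum(intr)
    if (!col %in% names(tb)) stop("tables lack responses for modality ", modality)
    num <- num + sum(intr & tb[[col]], na.rm = TRUE)
  }
  if (den == 0L) stop("no intradental cells pooled (denominator 0)")
  pct_raw <- 100 * num / den
  pct <- if (digits == 0L) round_half_up(pct_raw) else trunc_digits(pct_raw, digits)
  list(numerator = num, denominator = den, percent = pct)
}

#' Score per-cell per-channel expression positivity
#'
#' A channel is positive for a cell when the ROI's mean intensity exceeds the
#' background mean plus `k_sd` background SDs, with background statistics
#' taken from pixels outside all ROIs.
#'
#' @param channels H x W x C array (or list of matrices) aligned to the ROI
#'   grid.
#' @param rois an [roi_set()].
#' @param k_sd threshold in background SDs (default 2).
#' @return logical matrix (cells x channels) with dimnames.
#' @export
score_expression <- function(channels, rois, k_sd = 2) {
  if (is.list(channels)) {
    arr <- array(0, c(dim(channels[[1L]]), length(channels)))
    for (k in seq_along(channels)) arr[, , k] <- channels[[k]]
    channels <- arr
  }
  if (length(dim(channels)) == 2L) channels <- array(channels, c(dim(channels), 1L))
  stopifnot(all(dim(channels)[1:2] == rois$image_shape))
  bg <- !roi_union(rois)
  if (!any(bg)) stop("no background pixels outside ROIs")
  nc <- dim(channels)[3L]
  out <- matrix(FALSE, length(rois$rois), nc,
                dimnames = list(roi_ids(rois),
                                paste0("ch", seq_len(nc))))
  for (k in seq_len(nc)) {
    ch <- channels[, , k]
    mu <- mean(ch[bg]); s <- sd(ch[bg])
    if (is.na(s) || s == 0) s <- .Machine$double.eps
    thr <- mu + k_sd * s
    for (i in seq_along(rois$rois))
      out[i, k] <- mean(ch[rois$rois[[i]]$mask]) > thr
  }
  out
}
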