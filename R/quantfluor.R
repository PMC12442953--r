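# ROI-based immune-cell fluorescence quantification: nuclear-channel
# segmentation, morphological cleanup, two-stage background subtraction and
# area-normalized brightness.

#' Otsu threshold of an image
#'
#' Maximizes between-class variance on a 256-bin histogram between the image
#' min and max.
#'
#' @param image numeric matrix.
#' @return scalar threshold (image units).
#' @export
otsu_threshold <- function(image) {
  assert_image(image)
  v <- as.numeric(image)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  nb <- 256L
  edges <- seq(lo, hi, length.out = nb + 1L)
  h <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE), nb), nb)
  p <- h / sum(h)
  mids <- (edges[-1L] + edges[-(nb + 1L)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Quantification settings
#'
#' @param threshold_method `"otsu"` (default) or a fixed numeric threshold.
#' @param min_object_px drop connected components smaller than this
#'   (default 50 px).
#' @param fill_holes fill interior holes of surviving objects (default TRUE).
#' @param noise_channel_threshold `"otsu"` or a fixed value, used when a
#'   noise channel is supplied to [subtract_background()].
#' @param exclusion_mask optional logical image of out-of-tissue bright areas
#'   to zero out.
#' @return a `quant_config`.
#' @export
quant_config <- function(threshold_method = "otsu", min_object_px = 50L,
                         fill_holes = TRUE, noise_channel_threshold = "otsu",
                         exclusion_mask = NULL) {
  stopifnot(min_object_px >= 0)
  structure(list(threshold_method = threshold_method,
                 min_object_px = as.integer(min_object_px),
                 fill_holes = isTRUE(fill_holes),
                 noise_channel_threshold = noise_channel_threshold,
                 exclusion_mask = exclusion_mask),
            class = "quant_config")
}

resolve_threshold <- function(image, method) {
  if (is.numeric(method)) return(method)
  if (identical(method, "otsu")) return(otsu_threshold(image))
  stop("unknown threshold method")
}

#' Segment ROIs from the nuclear (DAPI) channel
#'
#' Threshold (Otsu by default), remove components below `min_object_px`,
#' fill holes, then zero out exclusion-mask pixels. Raises an error naming
#' the stage that emptied the mask.
#'
#' @param nuclear_channel numeric matrix.
#' @param cfg a [quant_config()].
#' @return logical ROI mask.
#' @export
segment_rois <- function(nuclear_channel, cfg = quant_config()) {
  assert_image(nuclear_channel)
  if (!is.null(cfg$exclusion_mask) &&
      !all(dim(cfg$exclusion_mask) == dim(nuclear_channel)))
    stop("exclusion mask shape mismatch")
  thr <- resolve_threshold(nuclear_channel, cfg$threshold_method)
  mask <- nuclear_channel > thr
  if (!any(mask)) stop("segmentation empty after thresholding")
  lab <- cpp_label(mask)
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= cfg$min_object_px)
  mask <- matrix(lab %in% keep & lab > 0L, nrow(mask), ncol(mask))
  if (!any(mask)) stop("segmentation empty after removing small objects")
  if (cfg$fill_holes) mask <- fill_holes_mask(mask)
  if (!is.null(cfg$exclusion_mask)) {
    mask <- mask & !(cfg$exclusion_mask > 0)
    if (!any(mask)) stop("segmentation empty after applying exclusion mask")
  }
  mask
}

#' Two-stage background subtraction of the signal channel
#'
#' Subtracts the scalar mean of the signal over non-ROI pixels from every
#' pixel; where the thresholded noise channel is positive, additionally
#' subtracts the noise-channel intensity; clamps at 0.
#'
#' @param signal_channel numeric matrix.
#' @param roi_mask logical matrix from [segment_rois()].
#' @param noise_channel optional numeric matrix of structured background
#'   (e.g. autofluorescence) to subtract where significant.
#' @param cfg a [quant_config()].
#' @param mask_noise if TRUE, zero out noise-positive pixels entirely
#'   instead of subtracting intensities.
#' @return corrected image (nonnegative).
#' @export
subtract_background <- function(signal_channel, roi_mask, noise_channel = NULL,
                                cfg = quant_config(), mask_noise = FALSE) {
  assert_image(signal_channel)
  if (!all(dim(roi_mask) == dim(signal_channel))) stop("shape mismatch")
  bg <- !roi_mask
  if (!any(bg)) stop("ROI mask covers the whole image: no background pixels")
  out <- signal_channel - mean(signal_channel[bg])
  if (!is.null(noise_channel)) {
    if (!all(dim(noise_channel) == dim(signal_channel))) stop("shape mismatch")
    nthr <- resolve_threshold(noise_channel, cfg$noise_channel_threshold)
    sig <- noise_channel > nthr
    if (mask_noise) out[sig] <- 0
    else out[sig] <- out[sig] - noise_channel[sig]
  }
  pmax(out, 0)
}

#' Area-normalized ROI brightness
#'
#' Total corrected fluorescence over the ROI mask divided by the mask area.
#'
#' @param corrected_signal image from [subtract_background()].
#' @param roi_mask logical matrix (nonempty).
#' @return scalar mean brightness.
#' @export
roi_brightness <- function(corrected_signal, roi_mask) {
  if (!any(roi_mask)) stop("empty ROI mask")
  sum(corrected_signal[roi_mask]) / sum(roi_mask)
}

#' End-to-end immune fluorescence quantification
#'
#' Convenience wrapper: segment the nuclear channel, correct the signal
#' channel, return pooled brightness.
#'
#' @param nuclear_channel,signal_channel numeric matrices.
#' @param noise_channel optional matrix.
#' @param cfg a [quant_config()].
#' @return list with `mask`, `corrected`, `roi_area_px`, `mean_brightness`.
#' @export
quantify_immune <- function(nuclear_channel, signal_channel,
                            noise_channel = NULL, cfg = quant_config()) {
  mask <- segment_rois(nuclear_channel, cfg)
  corr <- subtract_background(signal_channel, mask, noise_channel, cfg)
  list(mask = mask, corrected = corr, roi_area_px = sum(mask),
       mean_brightness = roi_brightness(corr, mask))
}
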