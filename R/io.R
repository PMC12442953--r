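# File I/O: minimal uncompressed grayscale TIFF (multi-page, 8/16-bit unsigned
# or 32-bit float), ROI JSON, trace CSV. The environment ships no TIFF reader,
# so the subset of baseline TIFF 6.0 used by the pipeline is implemented here.

#' Write a multi-page grayscale TIFF
#'
#' Writes uncompressed, single-sample, little-endian TIFF. Multi-frame input
#' becomes one page per frame.
#'
#' @param frames a numeric matrix, a list of matrices, or an H x W x T array.
#' @param path output path.
#' @param format `"uint16"` (default), `"uint8"`, or `"float32"`. Integer
#'   formats round and clamp to the representable range.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(frames, path, format = c("uint16", "uint8", "float32")) {
  format <- match.arg(format)
  pages <- as_frame_list(frames)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  writeBin(charToRaw("II"), con)
  w2(42L)
  bits <- switch(format, uint8 = 8L, uint16 = 16L, float32 = 32L)
  fmt <- if (format == "float32") 3L else 1L
  bytespp <- bits %/% 8L
  ntags <- 10L
  ifd_size <- 2L + 12L * ntags + 4L
  offs <- 8L
  page_meta <- lapply(pages, function(p) {
    m <- list(ifd = offs, data = offs + ifd_size,
              nbytes = nrow(p) * ncol(p) * bytespp)
    offs <<- offs + ifd_size + m$nbytes
    m
  })
  w4(page_meta[[1L]]$ifd)
  tag <- function(id, type, count, value) {
    w2(id); w2(type); w4(count)
    if (type == 3L) { w2(value); w2(0L) } else w4(value)
  }
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    m <- page_meta[[i]]
    w2(ntags)
    tag(256L, 4L, 1L, ncol(p))           # ImageWidth
    tag(257L, 4L, 1L, nrow(p))           # ImageLength
    tag(258L, 3L, 1L, bits)              # BitsPerSample
    tag(259L, 3L, 1L, 1L)                # Compression = none
    tag(262L, 3L, 1L, 1L)                # Photometric = BlackIsZero
    tag(273L, 4L, 1L, m$data)            # StripOffsets
    tag(277L, 3L, 1L, 1L)                # SamplesPerPixel
    tag(278L, 4L, 1L, nrow(p))           # RowsPerStrip
    tag(279L, 4L, 1L, m$nbytes)          # StripByteCounts
    tag(339L, 3L, 1L, fmt)               # SampleFormat
    w4(if (i < length(pages)) page_meta[[i + 1L]]$ifd else 0L)
    v <- as.numeric(t(p))                # row-major pixel order
    if (format == "float32") {
      writeBin(v, con, size = 4L, endian = "little")
    } else {
      top <- 2^bits - 1
      iv <- pmin(pmax(round(v), 0), top)
      if (format == "uint8") {
        writeBin(as.raw(iv), con)
      } else {
        writeBin(as.raw(rbind(iv %% 256, iv %/% 256)), con)
      }
    }
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF written by [write_tiff()]
#'
#' Supports uncompressed single-sample pages, 8/16-bit unsigned or 32-bit
#' float, little-endian, one strip per page.
#'
#' @param path TIFF path.
#' @param as_array return an H x W x T array (default) rather than a list.
#' @return numeric array or list of matrices.
#' @export
read_tiff <- function(path, as_array = TRUE) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 8L || rawToChar(raw[1:2]) != "II")
    stop("not a little-endian TIFF file: ", path)
  u16 <- function(o) as.integer(raw[o + 1L]) + 256L * as.integer(raw[o + 2L])
  u32 <- function(o) as.integer(raw[o + 1L]) + 256 * as.integer(raw[o + 2L]) +
    65536 * as.integer(raw[o + 3L]) + 16777216 * as.integer(raw[o + 4L])
  ifd <- u32(4L)
  pages <- list()
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (k in seq_len(n)) {
      o <- ifd + 2L + 12L * (k - 1L)
      id <- u16(o); type <- u16(o + 2L)
      val <- if (type == 3L) u16(o + 8L) else u32(o + 8L)
      tags[[as.character(id)]] <- val
    }
    w <- tags[["256"]]; h <- tags[["257"]]
    bits <- if (is.null(tags[["258"]])) 1L else tags[["258"]]
    fmt <- if (is.null(tags[["339"]])) 1L else tags[["339"]]
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1L)
      stop("compressed TIFF not supported")
    off <- tags[["273"]]
    npx <- h * w
    if (fmt == 3L) {
      v <- readBin(raw[(off + 1L):(off + 4L * npx)], "numeric", npx, size = 4L,
                   endian = "little")
    } else if (bits == 16L) {
      v <- readBin(raw[(off + 1L):(off + 2L * npx)], "integer", npx, size = 2L,
                   signed = FALSE, endian = "little")
    } else if (bits == 8L) {
      v <- as.integer(raw[(off + 1L):(off + npx)])
    } else stop("unsupported BitsPerSample: ", bits)
    pages[[length(pages) + 1L]] <- matrix(as.numeric(v), h, w, byrow = TRUE)
    ifd <- u32(ifd + 2L + 12L * n)
  }
  if (!as_array) return(pages)
  arr <- array(0, c(nrow(pages[[1L]]), ncol(pages[[1L]]), length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- pages[[t]]
  arr
}

as_frame_list <- function(frames) {
  if (is.matrix(frames)) return(list(frames))
  if (is.list(frames)) return(frames)
  if (is.array(frames) && length(dim(frames)) == 3L)
    return(lapply(seq_len(dim(frames)[3L]), function(t) frames[, , t]))
  stop("`frames` must be a matrix, list of matrices, or H x W x T array")
}

#' Write / read an ROI set as polygon-or-mask JSON
#'
#' Masks are stored run-length encoded by row to keep the file text-friendly.
#'
#' @param rois an [roi_set()].
#' @param path JSON path.
#' @return `path` / an [roi_set()].
#' @export
write_roi_json <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  enc <- lapply(rois$rois, function(r) {
    idx <- which(r$mask) - 1L
    list(id = r$id, pixels = idx)
  })
  jsonlite::write_json(list(image_shape = rois$image_shape, rois = enc), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi_json
#' @export
read_roi_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  shape <- as.integer(j$image_shape)
  masks <- lapply(seq_len(nrow(j$rois)), function(i) {
    m <- matrix(FALSE, shape[1L], shape[2L])
    m[unlist(j$rois$pixels[i]) + 1L] <- TRUE
    m
  })
  roi_set(masks, shape, ids = j$rois$id)
}

#' Write a trace matrix as CSV (rows = cells, columns = frames)
#'
#' A JSON sidecar (`<path>.json`) records frame rate and units.
#'
#' @param traces a trace matrix from [extract_traces()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_traces_csv <- function(traces, path) {
  df <- as.data.frame(unclass(traces))
  names(df) <- paste0("frame", seq_len(ncol(traces)) - 1L)
  df <- cbind(cell_id = attr(traces, "cell_ids"), df)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(frame_rate_hz = attr(traces, "frame_rate_hz"), units = "dF"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  side <- paste0(path, ".json")
  rate <- if (file.exists(side))
    jsonlite::read_json(side)$frame_rate_hz else NA_real_
  m <- as.matrix(df[, -1L, drop = FALSE])
  trace_matrix(m, cell_ids = as.character(df[[1L]]), frame_rate_hz = rate)
}
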