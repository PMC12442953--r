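#' @useDynLib dentsense, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile sd rnorm runif median approx fft dist
#' @importFrom utils write.csv read.csv head tail modifyList packageVersion
#' @importFrom tools md5sum
#' @importFrom grDevices chull
NULL

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific 31-bit sub-seed from a master seed.
derive_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(stream) * 7919L
}

assert_image <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x) || length(x) == 0L)
    stop(sprintf("`%s` must be a nonempty numeric matrix", name), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  invisible(x)
}

# Trapezoidal integral with unit spacing.
trapz_unit <- function(y) {
  n <- length(y)
  if (n < 2L) return(0)
  sum((y[-1L] + y[-n]) / 2)
}

# Round half away from zero (Prism-style percent rounding).
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Truncate (toward zero) at `digits` decimals; 22/27 -> 81.4 at one decimal.
trunc_digits <- function(x, digits = 1L) {
  m <- 10^digits
  trunc(x * m) / m
}

# Centered image coordinate grids (0-based pixel centers).
coord_grid <- function(h, w) {
  list(r = matrix(rep(0:(h - 1L), w), h, w),
       c = matrix(rep(0:(w - 1L), each = h), h, w))
}

# Central-difference spatial gradient of an image (edge rows/cols one-sided).
image_gradient <- function(img) {
  h <- nrow(img); w <- ncol(img)
  gr <- img; gc <- img
  if (h >= 3L) gr[2:(h - 1L), ] <- (img[3:h, ] - img[1:(h - 2L), ]) / 2
  if (h >= 2L) { gr[1L, ] <- img[2L, ] - img[1L, ]; gr[h, ] <- img[h, ] - img[h - 1L, ] } else gr[] <- 0
  if (w >= 3L) gc[, 2:(w - 1L)] <- (img[, 3:w] - img[, 1:(w - 2L)]) / 2
  if (w >= 2L) { gc[, 1L] <- img[, 2L] - img[, 1L]; gc[, w] <- img[, w] - img[, w - 1L] } else gc[] <- 0
  list(r = gr, c = gc)
}

# Downsample an image by an integer-ish factor with pre-blur (pyramid level).
pyr_down <- function(img, factor = 2) {
  sm <- cpp_gauss_blur(img, 0.5 * factor)
  h2 <- max(2L, floor(nrow(img) / factor))
  w2 <- max(2L, floor(ncol(img) / factor))
  resize_bilinear(sm, h2, w2)
}

# Bilinear resize preserving the 0-based pixel-center geometry.
resize_bilinear <- function(img, h2, w2) {
  h <- nrow(img); w <- ncol(img)
  sr <- if (h2 > 1L) (h - 1) / (h2 - 1) else 0
  sc <- if (w2 > 1L) (w - 1) / (w2 - 1) else 0
  g <- coord_grid(h2, w2)
  cpp_warp_map(img, g$r * sr, g$c * sc)
}
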