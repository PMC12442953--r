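# Butterworth band-pass design and zero-phase filtering. No DSP package is
# available in the target environment, so the classic pole-zero design
# (analog prototype -> band-pass transform -> bilinear) is implemented here
# and validated against closed-form gain expectations in the tests.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rk in r) p <- c(p, 0) - c(0, p * rk)
  p
}

polyval_c <- function(p, x) {
  acc <- 0 + 0i
  for (c in p) acc <- acc * x + c
  acc
}

# Digital Butterworth band-pass coefficients (b, a), highest order first in
# the conventional a[1] = 1 normalization. Gain is 1 at the geometric band
# center.
butter_bandpass <- function(order, low_hz, high_hz, fs) {
  stopifnot(order >= 1, low_hz > 0, high_hz > low_hz, high_hz < fs / 2)
  w1 <- 2 * fs * tan(pi * low_hz / fs)
  w2 <- 2 * fs * tan(pi * high_hz / fs)
  bw <- w2 - w1
  w0sq <- w1 * w2
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  poles <- unlist(lapply(p_lp, function(pk) {
    disc <- sqrt((pk * bw / 2)^2 - w0sq)
    c(pk * bw / 2 + disc, pk * bw / 2 - disc)
  }))
  fs2 <- 2 * fs
  zp <- (fs2 + poles) / (fs2 - poles)
  zz <- c(rep(1 + 0i, order), rep(-1 + 0i, order))
  b <- Re(poly_from_roots(zz))
  a <- Re(poly_from_roots(zp))
  wc <- 2 * pi * sqrt(low_hz * high_hz) / fs
  g <- abs(polyval_c(b + 0i, exp(1i * wc)) / polyval_c(a + 0i, exp(1i * wc)))
  list(b = b / g, a = a / a[1L])
}

# Causal IIR filter (direct form), a[1] assumed 1.
iir_filter <- function(b, a, x) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1L), x)
  v <- as.numeric(stats::filter(xp, b, method = "convolution", sides = 1))
  v <- v[nb:length(xp)]
  if (length(a) > 1L)
    v <- as.numeric(stats::filter(v, -a[-1L], method = "recursive"))
  v
}

# Zero-phase (forward-backward) filtering with odd-reflection padding.
filtfilt_bp <- function(b, a, x) {
  n <- length(x)
  np <- 3L * (max(length(a), length(b)) - 1L)
  if (n <= np) stop("signal too short for zero-phase filtering")
  head_pad <- 2 * x[1L] - x[(np + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - np)]
  xa <- c(head_pad, x, tail_pad)
  y <- iir_filter(b, a, xa)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(np + 1L):(np + n)]
}
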