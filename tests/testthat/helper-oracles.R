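# Independent oracles and small scene builders used across the suite.

# Sparse Gaussian-blob scene (plain R, no package internals).
blob_scene <- function(h = 96, w = 96, n = 8, seed = 1, bg = 10, amp = 80,
                       sig2 = 9) {
  set.seed(seed)
  sc <- matrix(bg, h, w)
  for (k in seq_len(n)) {
    cc <- runif(2, 0.18 * h, 0.8 * h)
    sc <- sc + amp * exp(-((row(sc) - 1 - cc[1])^2 +
                             (col(sc) - 1 - cc[2])^2) / (2 * sig2))
  }
  sc
}

# Integer shift of an image by plain indexing; returns the shifted image and
# a logical mask of valid (in-overlap) pixels.
shift_int <- function(img, dr, dc) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(NA_real_, h, w)
  src_r <- (1 + max(0, dr)):(h + min(0, dr))
  src_c <- (1 + max(0, dc)):(w + min(0, dc))
  out[src_r - dr, src_c - dc] <- img[src_r, src_c]
  out
}

# Exhaustive integer-shift search minimizing the mean squared difference
# over the overlap; independent of the gradient-descent path.
oracle_int_shift <- function(fixed, moving, max_shift = 10L) {
  best <- c(0, 0); best_ms <- Inf
  for (dr in -max_shift:max_shift)
    for (dc in -max_shift:max_shift) {
      sh <- shift_int(moving, dr, dc)
      ok <- !is.na(sh)
      ms <- mean((fixed[ok] - sh[ok])^2)
      if (ms < best_ms) { best_ms <- ms; best <- c(dr, dc) }
    }
  best
}

# Brute-force Feret oracle: max pairwise distance over boundary pixels + 1.
oracle_feret <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  h <- nrow(mask); w <- ncol(mask)
  bnd <- idx[apply(idx, 1, function(p) {
    i <- p[1]; j <- p[2]
    i == 1 || i == h || j == 1 || j == w ||
      !(mask[i - 1, j] && mask[i + 1, j] && mask[i, j - 1] && mask[i, j + 1])
  }), , drop = FALSE]
  if (nrow(bnd) < 2) return(1)
  max(dist(bnd)) + 1
}

# Brute-force Euclidean dilation oracle: pixels within `r` of any mask pixel.
oracle_dilate <- function(mask, r) {
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(mask)))
    for (j in seq_len(ncol(mask))) {
      d2 <- min((idx[, 1] - i)^2 + (idx[, 2] - j)^2)
      out[i, j] <- d2 <= r^2
    }
  out
}

# Registration error up to the global reference offset (alignment to an
# internal reference leaves one common translation undetermined).
shift_rms_error <- function(true_shift, transforms) {
  est <- -t(vapply(transforms, function(m) m$offset, numeric(2)))
  resid <- true_shift - est
  resid <- sweep(resid, 2, colMeans(resid))
  sqrt(mean(rowSums(resid^2)))
}
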