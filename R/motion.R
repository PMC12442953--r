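# Inter-frame motion correction: translation rough pass then affine
# fine-tuning, mean-squares similarity, regular-step gradient descent.

#' Movie stack container
#'
#' Holds a T-frame fluorescence movie as an H x W x T array with acquisition
#' metadata. Frames are in arbitrary fluorescence units and must be finite
#' and nonnegative.
#'
#' @param frames H x W x T numeric array (or list of matrices).
#' @param frame_rate_hz acquisition rate (Hz); the study's recordings were
#'   acquired at 5 Hz.
#' @param pixel_size_um pixel pitch in micrometres.
#' @return an object of class `movie_stack`.
#' @export
movie_stack <- function(frames, frame_rate_hz = 5, pixel_size_um = 1.625) {
  if (is.list(frames)) {
    arr <- array(0, c(nrow(frames[[1L]]), ncol(frames[[1L]]), length(frames)))
    for (t in seq_along(frames)) arr[, , t] <- frames[[t]]
    frames <- arr
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be positive")
  if (!all(is.finite(frames))) stop("frames contain non-finite values")
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz,
                 pixel_size_um = pixel_size_um),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("movie_stack: %d x %d px, %d frames @ %g Hz (%g um/px)\n",
              d[1L], d[2L], d[3L], x$frame_rate_hz, x$pixel_size_um))
  invisible(x)
}

n_frames <- function(movie) dim(movie$frames)[3L]

#' 2-D affine transform
#'
#' Maps output (fixed-grid) pixel coordinates `p` (0-based row/col, pixel
#' centers at integers) to input coordinates `linear %*% (p - center) +
#' center + offset`.
#'
#' @param linear 2 x 2 matrix (non-singular).
#' @param offset length-2 translation (px, row/col).
#' @param center length-2 rotation center (px); defaults to the image center
#'   when applied.
#' @return object of class `affine2d`.
#' @export
affine2d <- function(linear = diag(2), offset = c(0, 0), center = c(0, 0)) {
  linear <- matrix(as.numeric(linear), 2L, 2L)
  if (!all(is.finite(linear)) || abs(det(linear)) < .Machine$double.eps)
    stop("linear part must be finite and non-singular")
  structure(list(linear = linear, offset = as.numeric(offset),
                 center = as.numeric(center)),
            class = "affine2d")
}

#' @export
print.affine2d <- function(x, ...) {
  cat("affine2d: linear [", paste(signif(t(x$linear), 5), collapse = " "),
      "] offset (", paste(signif(x$offset, 5), collapse = ", "),
      ") center (", paste(signif(x$center, 5), collapse = ", "), ")\n")
  invisible(x)
}

image_center <- function(img) c((nrow(img) - 1) / 2, (ncol(img) - 1) / 2)

is_identity_affine <- function(t, tol = 0) {
  all(abs(t$linear - diag(2)) <= tol) && all(abs(t$offset) <= tol)
}

#' Compose two affine transforms
#'
#' `compose_affine(a, b)` returns the transform equivalent to applying `a`'s
#' mapping first and then `b`'s, i.e. `map(p) = b(a(p))` in coordinates.
#'
#' @param a,b `affine2d` objects (centers must agree).
#' @return an `affine2d`.
#' @export
compose_affine <- function(a, b) {
  stopifnot(inherits(a, "affine2d"), inherits(b, "affine2d"))
  if (!isTRUE(all.equal(a$center, b$center)))
    stop("compose_affine requires a common center")
  # b(a(p)) = B (A (p-c) + c + oa - c) + c + ob = BA (p-c) + c + B oa + ob
  affine2d(b$linear %*% a$linear, as.numeric(b$linear %*% a$offset) + b$offset,
           a$center)
}

#' Invert an affine transform
#' @param t an `affine2d`.
#' @return the inverse `affine2d` (same center).
#' @export
invert_affine <- function(t) {
  li <- solve(t$linear)
  affine2d(li, -as.numeric(li %*% t$offset), t$center)
}

#' Map points through an affine transform
#' @param t an `affine2d`.
#' @param pts n x 2 matrix of (row, col) coordinates.
#' @return n x 2 matrix of mapped coordinates.
#' @export
map_points_affine <- function(t, pts) {
  pts <- matrix(pts, ncol = 2L)
  sweep(t(t$linear %*% (t(pts) - t$center)), 2L, t$center + t$offset, "+")
}

#' Optimizer settings for regular-step gradient descent
#'
#' The optimizer steps along the negative normalized gradient with the
#' current step length; when the gradient direction reverses, the step is
#' multiplied by `relaxation`; iteration stops at `min_step` or
#' `max_iterations`.
#'
#' @param initial_step starting step length (px for translation; scaled
#'   parameter units for affine).
#' @param min_step convergence threshold on the step length.
#' @param max_iterations iteration cap.
#' @param relaxation step multiplier applied on gradient sign change, in (0,1).
#' @return an `optimizer_config`.
#' @export
optimizer_config <- function(initial_step = 2.0, min_step = 0.01,
                             max_iterations = 200L, relaxation = 0.5) {
  stopifnot(min_step > 0, min_step <= initial_step, max_iterations >= 1,
            relaxation > 0, relaxation < 1)
  structure(list(initial_step = initial_step, min_step = min_step,
                 max_iterations = as.integer(max_iterations),
                 relaxation = relaxation),
            class = "optimizer_config")
}

#' Mean-squares image similarity
#'
#' Mean of squared pixel differences over the overlap domain. For two images
#' on the same grid the overlap is the full grid; when `transform` is given,
#' fixed pixels whose mapped coordinate falls outside the moving grid are
#' excluded.
#'
#' @param fixed,moving numeric matrices of equal shape.
#' @param transform optional `affine2d` applied to `moving`.
#' @return scalar metric value.
#' @export
mean_squares <- function(fixed, moving, transform = NULL) {
  assert_image(fixed); assert_image(moving)
  if (!all(dim(fixed) == dim(moving))) stop("image shapes differ")
  if (is.null(transform)) return(mean((fixed - moving)^2))
  cpp_ms_affine(fixed, moving, as.numeric(t(transform$linear)),
                transform$offset, transform$center)$ms
}

#' Resample an image through an affine transform
#'
#' Bilinear interpolation; out-of-domain pixels are set to 0. Applying the
#' identity returns the input bit-exactly.
#'
#' @param image numeric matrix.
#' @param t an `affine2d`.
#' @return resampled matrix (same shape).
#' @export
apply_transform <- function(image, t) {
  assert_image(image)
  stopifnot(inherits(t, "affine2d"))
  cpp_warp_affine(image, as.numeric(t(t$linear)), t$offset, t$center)
}

# Metric subsampling stride for the optimizer inner loop: keep at least
# ~4000 sampled pixels. The final reported metric always uses the full grid.
metric_stride <- function(d) {
  max(1L, floor(sqrt(prod(d) / 4000)))
}

# Regular-step gradient descent over a parameter vector. `metric_fn(par)`
# returns the metric; `scales` converts optimizer space to parameter space
# (par = q / scales). Tracks and returns the best-seen parameters so the
# final metric never exceeds the initial one.
regular_step_descent <- function(par0, metric_fn, opt, scales = NULL,
                                 grad_h = 0.25) {
  np <- length(par0)
  if (is.null(scales)) scales <- rep(1, np)
  q <- par0 * scales
  grad_q <- function(q) {
    g <- numeric(np)
    for (k in seq_len(np)) {
      e <- numeric(np); e[k] <- grad_h
      g[k] <- (metric_fn((q + e) / scales) - metric_fn((q - e) / scales)) /
        (2 * grad_h)
    }
    g
  }
  best_par <- par0
  best_m <- metric_fn(par0)
  step <- opt$initial_step
  g <- grad_q(q)
  iters <- 0L
  converged <- FALSE
  stall <- 0L
  degenerate <- sqrt(sum(g^2)) == 0
  while (!degenerate && iters < opt$max_iterations) {
    iters <- iters + 1L
    gn <- sqrt(sum(g^2))
    if (gn == 0) break
    q_new <- q - step * g / gn
    m_new <- metric_fn(q_new / scales)
    if (m_new < best_m * (1 - 1e-8)) {
      best_m <- m_new; best_par <- q_new / scales; stall <- 0L
    } else stall <- stall + 1L
    g_new <- grad_q(q_new)
    if (sum(g_new * g) < 0) step <- step * opt$relaxation
    q <- q_new
    g <- g_new
    if (step < opt$min_step || stall >= 25L) { converged <- TRUE; break }
  }
  list(par = best_par, metric = best_m, iterations = iters,
       converged = converged && !degenerate, degenerate = degenerate)
}

#' Estimate a translation aligning `moving` to `fixed`
#'
#' Rough-approximation stage: translation-only registration minimizing
#' [mean_squares()] by regular-step gradient descent. The returned transform
#' has an identity linear part.
#'
#' @param fixed,moving equal-shape images; must not be constant.
#' @param opt an [optimizer_config()].
#' @param init_offset starting offset (px); warm-starting from the previous
#'   frame's estimate keeps a movie's smooth motion inside the metric's
#'   capture range.
#' @return an `affine2d` with attributes `converged`, `iterations`,
#'   `initial_metric`, `final_metric`.
#' @export
estimate_translation <- function(fixed, moving, opt = optimizer_config(),
                                 init_offset = c(0, 0)) {
  assert_image(fixed); assert_image(moving)
  if (!all(dim(fixed) == dim(moving))) stop("image shapes differ")
  cen <- image_center(fixed)
  lin <- c(1, 0, 0, 1)
  stride <- metric_stride(dim(fixed))
  metric <- function(par) cpp_ms_affine(fixed, moving, lin, par, cen, stride)$ms
  res <- regular_step_descent(as.numeric(init_offset), metric, opt)
  out <- affine2d(diag(2), res$par, cen)
  if (res$degenerate) {
    warning("zero metric gradient (constant image?); returning identity")
    out <- affine2d(diag(2), c(0, 0), cen)
  }
  attr(out, "converged") <- res$converged
  attr(out, "iterations") <- res$iterations
  attr(out, "initial_metric") <- mean_squares(fixed, moving)
  attr(out, "final_metric") <- mean_squares(fixed, moving, out)
  out
}

#' Refine a full affine transform from an initial estimate
#'
#' Fine-tuning stage: all six affine parameters are optimized by regular-step
#' gradient descent on [mean_squares()], with parameter scaling so a unit
#' optimizer step moves the image comparably through matrix entries and
#' offset. The final metric never exceeds the metric at `init`.
#'
#' @param fixed,moving equal-shape images.
#' @param init starting `affine2d` (e.g. from [estimate_translation()]).
#' @param opt an [optimizer_config()]; the affine stage defaults to a smaller
#'   `initial_step` (0.1).
#' @return an `affine2d` with convergence attributes as in
#'   [estimate_translation()].
#' @export
refine_affine <- function(fixed, moving, init = NULL,
                          opt = optimizer_config(initial_step = 0.1,
                                                 min_step = 1e-4)) {
  assert_image(fixed); assert_image(moving)
  if (!all(dim(fixed) == dim(moving))) stop("image shapes differ")
  cen <- image_center(fixed)
  if (is.null(init)) init <- affine2d(diag(2), c(0, 0), cen)
  stopifnot(inherits(init, "affine2d"))
  par0 <- c(as.numeric(t(init$linear)), init$offset)
  scales <- c(rep(1, 4), rep(1 / max(dim(fixed)), 2))
  stride <- metric_stride(dim(fixed))
  metric <- function(par)
    cpp_ms_affine(fixed, moving, par[1:4], par[5:6], cen, stride)$ms
  res <- regular_step_descent(par0, metric, opt, scales = scales, grad_h = 0.02)
  par <- res$par
  out <- affine2d(matrix(par[1:4], 2L, 2L, byrow = TRUE), par[5:6], cen)
  if (res$degenerate) {
    warning("zero metric gradient (constant image?); returning init")
    out <- init
  }
  # contract: never worse than the initialization on the full grid
  if (mean_squares(fixed, moving, out) > mean_squares(fixed, moving, init))
    out <- init
  attr(out, "converged") <- res$converged
  attr(out, "iterations") <- res$iterations
  attr(out, "initial_metric") <- mean_squares(fixed, moving, init)
  attr(out, "final_metric") <- mean_squares(fixed, moving, out)
  out
}

#' Register every frame of a movie to a reference image
#'
#' Each frame passes through [estimate_translation()] then [refine_affine()]
#' and is resampled onto the reference grid. Per-frame non-convergence is
#' collected as warnings attached to the result; the stack is never aborted.
#'
#' @param movie a [movie_stack()].
#' @param opt an [optimizer_config()] for the translation stage; the affine
#'   stage reuses it with `initial_step = 0.1`.
#' @param reference `"mean"` (default, mean projection of the unregistered
#'   stack) or `"first"`.
#' @return list with `movie` (registered [movie_stack()]), `transforms`
#'   (per-frame `affine2d`), `metrics` (data.frame of pre/post mean-squares),
#'   and `warnings` (character).
#' @export
register_stack <- function(movie, opt = optimizer_config(),
                           reference = c("mean", "first")) {
  stopifnot(inherits(movie, "movie_stack"))
  reference <- match.arg(reference)
  T <- n_frames(movie)
  if (T < 2L) stop("register_stack needs at least 2 frames")
  ref <- if (reference == "mean") apply(movie$frames, c(1, 2), mean)
         else movie$frames[, , 1L]
  opt_aff <- optimizer_config(initial_step = 0.1,
                              min_step = min(opt$min_step, 1e-4),
                              max_iterations = opt$max_iterations,
                              relaxation = opt$relaxation)
  transforms <- vector("list", T)
  warnings <- character(0)
  pre <- post <- numeric(T)
  out <- movie$frames
  prev_offset <- c(0, 0)
  for (t in seq_len(T)) {
    fr <- movie$frames[, , t]
    tr <- withCallingHandlers(
      estimate_translation(ref, fr, opt, init_offset = prev_offset),
      warning = function(w) {
        warnings <<- c(warnings, sprintf("frame %d: %s", t, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    aff <- withCallingHandlers(
      refine_affine(ref, fr, tr, opt_aff),
      warning = function(w) {
        warnings <<- c(warnings, sprintf("frame %d: %s", t, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    if (!isTRUE(attr(aff, "converged")))
      warnings <- c(warnings, sprintf("frame %d: optimizer stopped before min_step", t))
    pre[t] <- mean_squares(ref, fr)
    post[t] <- attr(aff, "final_metric")
    # guard: never worsen the metric relative to no correction
    if (post[t] > pre[t]) {
      aff <- affine2d(diag(2), c(0, 0), image_center(ref))
      post[t] <- pre[t]
      warnings <- c(warnings, sprintf("frame %d: registration rejected (metric increase)", t))
    }
    prev_offset <- tr$offset
    transforms[[t]] <- aff
    out[, , t] <- if (is_identity_affine(aff)) fr else apply_transform(fr, aff)
  }
  reg <- movie_stack(out, movie$frame_rate_hz, movie$pixel_size_um)
  structure(list(movie = reg, transforms = transforms,
                 metrics = data.frame(frame = seq_len(T), pre = pre, post = post),
                 reference = ref, warnings = warnings),
            class = "stack_registration")
}

#' @export
print.stack_registration <- function(x, ...) {
  cat(sprintf("stack_registration: %d frames, mean MS %.4g -> %.4g, %d warning(s)\n",
              nrow(x$metrics), mean(x$metrics$pre), mean(x$metrics$post),
              length(x$warnings)))
  invisible(x)
}

#' Serialize affine transforms to JSON
#' @param transforms list of `affine2d`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_transforms_json <- function(transforms, path) {
  enc <- lapply(transforms, function(t)
    list(linear = as.numeric(t(t$linear)), offset = t$offset, center = t$center))
  jsonlite::write_json(enc, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transforms_json
#' @export
read_transforms_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(j)), function(i)
    affine2d(matrix(unlist(j$linear[i]), 2L, 2L, byrow = TRUE),
             unlist(j$offset[i]), unlist(j$center[i])))
}
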