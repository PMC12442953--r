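# Post hoc ISH alignment: percentile normalization, control-point
# second-order polynomial initialization, multiresolution Demons refinement,
# warp application, ROI transfer, and labeling efficiency/specificity.

#' Percentile intensity normalization
#'
#' Linearly maps the `p_low` percentile to 0 and the `p_high` percentile to
#' 1, then clips to `[0, 1]`. Applied to both images before any registration
#' step.
#'
#' @param image numeric matrix.
#' @param p_low,p_high percentiles (defaults 0.1 and 99.9).
#' @return normalized matrix in `[0, 1]`.
#' @export
normalize_percentiles <- function(image, p_low = 0.1, p_high = 99.9) {
  assert_image(image)
  q <- quantile(image, c(p_low, p_high) / 100, names = FALSE)
  if (q[2L] <= q[1L]) {
    warning("degenerate percentile range (constant image); returning zeros")
    return(matrix(0, nrow(image), ncol(image)))
  }
  pmin(pmax((image - q[1L]) / (q[2L] - q[1L]), 0), 1)
}

#' Control-point pairs for polynomial initialization
#'
#' @param fixed,moving n x 2 matrices of matched (row, col) coordinates in
#'   px; at least 6 pairs are required for a second-order fit.
#' @return a `control_points` object.
#' @export
control_points <- function(fixed, moving) {
  fixed <- matrix(as.numeric(fixed), ncol = 2L)
  moving <- matrix(as.numeric(moving), ncol = 2L)
  if (nrow(fixed) != nrow(moving)) stop("point counts differ")
  if (nrow(fixed) < 6L) stop("need at least 6 control-point pairs")
  if (anyDuplicated(fixed)) stop("duplicated fixed points")
  if (!all(is.finite(fixed)) || !all(is.finite(moving)))
    stop("control points must be finite")
  structure(list(fixed = fixed, moving = moving), class = "control_points")
}

#' @rdname control_points
#' @param path JSON file with `{"pairs": [[[r_f,c_f],[r_m,c_m]], ...]}`.
#' @export
read_control_points <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- j$pairs
  control_points(t(sapply(seq_len(dim(p)[1L]), function(i) p[i, 1L, ])),
                 t(sapply(seq_len(dim(p)[1L]), function(i) p[i, 2L, ])))
}

#' @rdname control_points
#' @param points a `control_points` object to serialize.
#' @export
write_control_points <- function(points, path) {
  pairs <- lapply(seq_len(nrow(points$fixed)), function(i)
    list(points$fixed[i, ], points$moving[i, ]))
  jsonlite::write_json(list(pairs = pairs), path, digits = NA)
  invisible(path)
}

poly2_basis <- function(pts) {
  r <- pts[, 1L]; c <- pts[, 2L]
  cbind(1, r, c, r^2, r * c, c^2)
}

#' Fit a second-order polynomial warp from control points
#'
#' Least-squares fit of each moving coordinate on the 6-term basis
#' `{1, r, c, r^2, rc, c^2}` of the fixed coordinates. Exactly consistent
#' points give zero residual.
#'
#' @param points a [control_points()] object.
#' @return a `polywarp2` with `coeffs` (6 x 2: row and col coefficient
#'   columns) and `rms_residual_px`.
#' @export
fit_polynomial_warp <- function(points) {
  stopifnot(inherits(points, "control_points"))
  X <- poly2_basis(points$fixed)
  qrX <- qr(X)
  if (qrX$rank < 6L)
    stop("rank-deficient design matrix: fixed points lie on a conic; ",
         "spread control points across the field")
  coeffs <- qr.coef(qrX, points$moving)
  fitted <- X %*% coeffs
  structure(list(coeffs = coeffs,
                 rms_residual_px = sqrt(mean((fitted - points$moving)^2))),
            class = "polywarp2")
}

#' Identity polynomial warp
#' @return a `polywarp2` mapping every point to itself.
#' @export
polywarp_identity <- function() {
  structure(list(coeffs = matrix(c(0, 1, 0, 0, 0, 0,
                                   0, 0, 1, 0, 0, 0), 6L, 2L),
                 rms_residual_px = 0),
            class = "polywarp2")
}

#' Map points through a polynomial warp
#' @param warp a `polywarp2`.
#' @param pts n x 2 (row, col) matrix of fixed-grid coordinates.
#' @return n x 2 matrix of moving-grid coordinates.
#' @export
map_points_poly <- function(warp, pts) {
  pts <- matrix(pts, ncol = 2L)
  poly2_basis(pts) %*% warp$coeffs
}

poly_coord_maps <- function(warp, h, w) {
  g <- coord_grid(h, w)
  pts <- cbind(as.numeric(g$r), as.numeric(g$c))
  m <- map_points_poly(warp, pts)
  list(r = matrix(m[, 1L], h, w), c = matrix(m[, 2L], h, w))
}

#' Demons refinement settings
#'
#' Defaults follow the four-level schedule with decreasing iterations
#' `[5, 1, 1, 1]` assigned coarse to fine.
#'
#' @param n_levels pyramid depth (default 4).
#' @param iterations_per_level iterations per level, coarse first.
#' @param downsample_factor per-level downsampling (default 2).
#' @param smoothing_sigma_px Gaussian regularization of the displacement
#'   field after each iteration (default 1.5 px at each level).
#' @return a `demons_config`.
#' @export
demons_config <- function(n_levels = 4L, iterations_per_level = c(5L, 1L, 1L, 1L),
                          downsample_factor = 2, smoothing_sigma_px = 1.5) {
  stopifnot(length(iterations_per_level) == n_levels,
            all(iterations_per_level >= 1), downsample_factor > 1)
  structure(list(n_levels = as.integer(n_levels),
                 iterations_per_level = as.integer(iterations_per_level),
                 downsample_factor = downsample_factor,
                 smoothing_sigma_px = smoothing_sigma_px),
            class = "demons_config")
}

#' Warp model: polynomial initialization plus dense displacement
#'
#' The composed mapping is `map(p) = poly(p) + disp(p)` on the fixed grid.
#'
#' @param polynomial a `polywarp2`.
#' @param displacement H x W x 2 array (row/col components, px) or NULL for
#'   zero displacement.
#' @param shape fixed-grid (H, W), required when `displacement` is NULL.
#' @return a `warp_model`.
#' @export
warp_model <- function(polynomial, displacement = NULL, shape = NULL) {
  stopifnot(inherits(polynomial, "polywarp2"))
  if (is.null(displacement)) {
    stopifnot(!is.null(shape))
    displacement <- array(0, c(shape[1L], shape[2L], 2L))
  }
  stopifnot(length(dim(displacement)) == 3L, dim(displacement)[3L] == 2L,
            all(is.finite(displacement)))
  structure(list(polynomial = polynomial, displacement = displacement),
            class = "warp_model")
}

#' Map fixed-grid points through a warp model
#'
#' Exactly `poly(p)` plus the (bilinearly interpolated) displacement at `p`.
#'
#' @param model a [warp_model()].
#' @param pts n x 2 matrix of fixed-grid (row, col) coordinates.
#' @return n x 2 matrix of moving-grid coordinates.
#' @export
warp_points <- function(model, pts) {
  pts <- matrix(pts, ncol = 2L)
  out <- map_points_poly(model$polynomial, pts)
  pr <- matrix(pts[, 1L], 1L); pc <- matrix(pts[, 2L], 1L)
  out[, 1L] <- out[, 1L] +
    as.numeric(cpp_warp_map(model$displacement[, , 1L], pr, pc))
  out[, 2L] <- out[, 2L] +
    as.numeric(cpp_warp_map(model$displacement[, , 2L], pr, pc))
  out
}

warp_coord_maps <- function(model) {
  d <- dim(model$displacement)
  pm <- poly_coord_maps(model$polynomial, d[1L], d[2L])
  list(r = pm$r + model$displacement[, , 1L],
       c = pm$c + model$displacement[, , 2L])
}

#' Demons non-rigid refinement of a polynomial initialization
#'
#' Classic intensity-driven Demons on a Gaussian pyramid: at each level, the
#' displacement field is updated by
#' `u += diff * grad(fixed) / (|grad|^2 + diff^2)` and smoothed with a
#' Gaussian after every iteration, coarse to fine, upsampling the field
#' between levels. Both images are percentile-normalized internally. If the
#' refinement cannot improve on the polynomial-only metric the returned
#' model carries zero displacement and a warning is raised.
#'
#' @param fixed,moving equal-shape images (guidepost channels).
#' @param init a `polywarp2` (default identity).
#' @param cfg a [demons_config()].
#' @return a [warp_model()] with attribute `metrics` (data.frame: per-level
#'   full-resolution mean-squares after that level, plus the polynomial-only
#'   metric as level 0).
#' @export
demons_refine <- function(fixed, moving, init = polywarp_identity(),
                          cfg = demons_config()) {
  assert_image(fixed); assert_image(moving)
  if (!all(dim(fixed) == dim(moving))) stop("image shapes differ")
  fixed <- normalize_percentiles(fixed)
  moving <- normalize_percentiles(moving)
  h <- nrow(fixed); w <- ncol(fixed)

  # image pyramids, fine (index 1) to coarse (index n_levels)
  fpyr <- list(fixed); mpyr <- list(moving)
  for (k in seq_len(cfg$n_levels - 1L)) {
    fpyr[[k + 1L]] <- pyr_down(fpyr[[k]], cfg$downsample_factor)
    mpyr[[k + 1L]] <- pyr_down(mpyr[[k]], cfg$downsample_factor)
  }

  full_metric <- function(disp) {
    m <- warp_coord_maps(warp_model(init, disp))
    cpp_ms_map(fixed, moving, m$r, m$c)$ms
  }
  ms0 <- full_metric(array(0, c(h, w, 2L)))

  level_metrics <- numeric(cfg$n_levels)
  u_r <- u_c <- NULL
  for (lv in seq(cfg$n_levels, 1L)) {
    fk <- fpyr[[lv]]; mk <- mpyr[[lv]]
    hk <- nrow(fk); wk <- ncol(fk)
    # full->level coordinate scale (pixel-center geometry)
    sr <- if (hk > 1L) (h - 1) / (hk - 1) else 1
    sc <- if (wk > 1L) (w - 1) / (wk - 1) else 1
    if (is.null(u_r)) {
      u_r <- matrix(0, hk, wk); u_c <- matrix(0, hk, wk)
    } else {
      prev_h <- nrow(u_r)
      scale_r <- if (prev_h > 1L) (hk - 1) / (prev_h - 1) else 1
      scale_c <- if (ncol(u_r) > 1L) (wk - 1) / (ncol(u_r) - 1) else 1
      u_r <- resize_bilinear(u_r, hk, wk) * scale_r
      u_c <- resize_bilinear(u_c, hk, wk) * scale_c
    }
    # polynomial mapping expressed in level-k coordinates
    g <- coord_grid(hk, wk)
    pts <- cbind(as.numeric(g$r) * sr, as.numeric(g$c) * sc)
    pm <- map_points_poly(init, pts)
    poly_r <- matrix(pm[, 1L] / sr, hk, wk)
    poly_c <- matrix(pm[, 2L] / sc, hk, wk)
    grad <- image_gradient(fk)
    n_it <- cfg$iterations_per_level[cfg$n_levels - lv + 1L] # coarse first
    u_r_in <- u_r; u_c_in <- u_c
    for (it in seq_len(n_it)) {
      warped <- cpp_warp_map(mk, poly_r + u_r, poly_c + u_c)
      diff <- fk - warped
      # symmetric forces: average fixed and warped-moving gradients
      gw <- image_gradient(warped)
      jr <- (grad$r + gw$r) / 2
      jc <- (grad$c + gw$c) / 2
      denom <- jr^2 + jc^2 + diff^2
      step <- ifelse(denom > 1e-9, diff / denom, 0)
      # fluid-like regularization: smooth the incremental update, not the
      # accumulated field, so coarse-level structure is not diffused away
      u_r <- u_r + cpp_gauss_blur(step * jr, cfg$smoothing_sigma_px)
      u_c <- u_c + cpp_gauss_blur(step * jc, cfg$smoothing_sigma_px)
    }
    # record the full-resolution metric after this level; revert a level
    # that worsened it (trust check; keeps the pyramid metric monotone)
    to_full <- function(ur, uc) {
      fr <- resize_bilinear(ur, h, w) * (if (hk > 1L) (h - 1) / (hk - 1) else 1)
      fc <- resize_bilinear(uc, h, w) * (if (wk > 1L) (w - 1) / (wk - 1) else 1)
      array(c(fr, fc), c(h, w, 2L))
    }
    m_new <- full_metric(to_full(u_r, u_c))
    m_prev <- if (lv == cfg$n_levels) ms0
              else level_metrics[cfg$n_levels - lv]
    if (m_new > m_prev) {
      u_r <- u_r_in; u_c <- u_c_in
      m_new <- full_metric(to_full(u_r, u_c))
      if (m_new > m_prev) m_new <- m_prev # interpolation residue only
    }
    level_metrics[cfg$n_levels - lv + 1L] <- m_new
  }
  disp <- array(c(resize_bilinear(u_r, h, w), resize_bilinear(u_c, h, w)),
                c(h, w, 2L))
  ms_final <- full_metric(disp)
  if (!is.finite(ms_final) || ms_final > ms0) {
    warning("Demons could not improve on the polynomial initialization; ",
            "returning zero displacement")
    disp <- array(0, c(h, w, 2L))
    ms_final <- ms0
  }
  out <- warp_model(init, disp)
  attr(out, "metrics") <- data.frame(
    level = 0:cfg$n_levels,
    mean_squares = c(ms0, level_metrics))
  out
}

#' Apply a warp model to a multichannel image stack
#'
#' Every channel is resampled through the same composed transform (bilinear)
#' onto the fixed grid; channel order is preserved.
#'
#' @param stack H x W x C array or list of matrices on the moving grid.
#' @param model a [warp_model()] whose displacement matches the fixed grid.
#' @return array/list matching the input form, on the fixed grid.
#' @export
apply_warp_stack <- function(stack, model) {
  stopifnot(inherits(model, "warp_model"))
  maps <- warp_coord_maps(model)
  was_list <- is.list(stack)
  frames <- as_frame_list(stack)
  out <- lapply(frames, function(ch) {
    cpp_warp_map(ch, maps$r, maps$c)
  })
  if (was_list) return(out)
  arr <- array(0, c(dim(out[[1L]]), length(out)))
  for (k in seq_along(out)) arr[, , k] <- out[[k]]
  arr
}

fill_holes_mask <- function(mask) {
  lab <- cpp_label(!mask)
  if (max(lab) == 0L) return(mask)
  border <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)]))
  border <- setdiff(border, 0L)
  mask | (lab > 0L & !(lab %in% border))
}

#' Transfer ROIs between fixed and moving grids
#'
#' With `target = "fixed"` (default) the aligned ISH stack already lives on
#' the fixed grid, so the overlay is the identity. With `target = "moving"`
#' each ROI mask is mapped through the composed transform with
#' nearest-neighbour label placement (small rasterization holes are filled),
#' preserving label identity. ROIs mapped fully outside the target grid are
#' dropped with a warning.
#'
#' @param rois [roi_set()] on the fixed grid.
#' @param model a [warp_model()].
#' @param target `"fixed"` or `"moving"`.
#' @param moving_shape (H, W) of the moving grid; defaults to the fixed
#'   shape.
#' @return an [roi_set()]; attribute `dropped` lists ids of lost ROIs.
#' @export
transfer_rois <- function(rois, model, target = c("fixed", "moving"),
                          moving_shape = NULL) {
  target <- match.arg(target)
  if (target == "fixed") return(rois)
  if (is.null(moving_shape)) moving_shape <- rois$image_shape
  masks <- list(); ids <- character(0); dropped <- character(0)
  for (r in rois$rois) {
    px <- which(r$mask, arr.ind = TRUE) - 1L
    # supersample each source pixel (2x2) so the forward splat neither
    # leaves holes nor relies on hole-filling to reconstruct area
    px <- rbind(px + rep(c(-0.25, -0.25), each = nrow(px)),
                px + rep(c(-0.25, 0.25), each = nrow(px)),
                px + rep(c(0.25, -0.25), each = nrow(px)),
                px + rep(c(0.25, 0.25), each = nrow(px)))
    q <- warp_points(model, px)
    qi <- round(q)
    keep <- qi[, 1L] >= 0 & qi[, 1L] < moving_shape[1L] &
      qi[, 2L] >= 0 & qi[, 2L] < moving_shape[2L]
    if (!any(keep)) {
      dropped <- c(dropped, r$id)
      warning("ROI mapped fully outside the target grid: ", r$id)
      next
    }
    m <- matrix(FALSE, moving_shape[1L], moving_shape[2L])
    m[cbind(qi[keep, 1L] + 1L, qi[keep, 2L] + 1L)] <- TRUE
    masks[[length(masks) + 1L]] <- fill_holes_mask(m)
    ids <- c(ids, r$id)
  }
  if (!length(masks)) stop("all ROIs dropped during transfer")
  out <- roi_set(masks, moving_shape, ids = ids)
  attr(out, "dropped") <- dropped
  out
}

#' Labeling efficiency and specificity
#'
#' Efficiency: percent of neurons carrying the reporter. Specificity:
#' percent of reporter-positive neurons that also carry the molecular
#' marker. With zero reporter-positive cells specificity is undefined and
#' reported as `NA`.
#'
#' @param label_calls logical per-cell reporter calls.
#' @param marker_calls logical per-cell marker calls (same cells).
#' @return list with `efficiency` and `specificity` (percent).
#' @export
efficiency_specificity <- function(label_calls, marker_calls) {
  stopifnot(length(label_calls) == length(marker_calls),
            length(label_calls) > 0L)
  npos <- sum(label_calls)
  eff <- 100 * npos / length(label_calls)
  spec <- if (npos == 0L) {
    message("no reporter-positive cells: specificity undefined")
    NA_real_
  } else 100 * sum(label_calls & marker_calls) / npos
  list(efficiency = eff, specificity = spec)
}
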