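#' Apply a rigid transform (rotation + translation) to an image
#'
#' Rotates the image by `angle_deg` about `center` (0-based `(x, y)` pixel
#' coordinates) and then translates it by `shift` pixels, using inverse
#' mapping with bilinear interpolation. Pixels mapped from outside the
#' source are filled with `fill`.
#'
#' @param image numeric matrix.
#' @param angle_deg rotation angle in degrees (counter-clockwise in the
#'   `(x, y)` frame with y pointing down the rows).
#' @param shift numeric(2) translation `(dx, dy)` in pixels.
#' @param center numeric(2) rotation center `(x, y)`, 0-based; defaults to
#'   the image center.
#' @param fill background fill value.
#' @return transformed numeric matrix, same dimensions.
#' @export
transform_rigid <- function(image, angle_deg = 0, shift = c(0, 0),
                            center = NULL, fill = 0) {
  stopifnot(is.matrix(image))
  H <- nrow(image); W <- ncol(image)
  if (is.null(center)) center <- c((W - 1) / 2, (H - 1) / 2)
  th <- angle_deg * pi / 180
  # output pixel (x, y): inverse map = undo shift, rotate by -theta
  xs <- matrix(rep(0:(W - 1), each = H), H, W) - shift[1] - center[1]
  ys <- matrix(rep(0:(H - 1), W), H, W) - shift[2] - center[2]
  sx <- cos(th) * xs + sin(th) * ys + center[1]
  sy <- -sin(th) * xs + cos(th) * ys + center[2]
  .bilinear_sample(image, sx, sy, fill)
}

.bilinear_sample <- function(image, sx, sy, fill) {
  H <- nrow(image); W <- ncol(image)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  get <- function(xi, yi) {
    ok <- xi >= 0 & xi <= (W - 1) & yi >= 0 & yi <= (H - 1)
    v <- matrix(fill, nrow(sx), ncol(sx))
    v[ok] <- image[cbind(yi[ok] + 1L, xi[ok] + 1L)]
    v
  }
  get(x0, y0) * (1 - fx) * (1 - fy) +
    get(x0 + 1, y0) * fx * (1 - fy) +
    get(x0, y0 + 1) * (1 - fx) * fy +
    get(x0 + 1, y0 + 1) * fx * fy
}

# Integer-pixel translation estimate of b relative to a by FFT
# cross-correlation on mean-subtracted images. Returns list(shift, score):
# applying transform_rigid(b, 0, shift) best aligns b onto a.
.xcorr_shift <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  cc <- Re(stats::fft(stats::fft(am) * Conj(stats::fft(bm)), inverse = TRUE))
  idx <- which.max(cc)
  H <- nrow(a); W <- ncol(a)
  dy <- (idx - 1L) %% H
  dx <- (idx - 1L) %/% H
  if (dy > H / 2) dy <- dy - H
  if (dx > W / 2) dx <- dx - W
  list(shift = c(dx, dy), score = max(cc))
}

# Alignment score of frame against reference under a candidate rotation:
# rotate, then find the best translation by cross-correlation.
.rigid_score <- function(reference, frame, angle, center, fill) {
  rot <- if (angle == 0) frame else
    transform_rigid(frame, angle, c(0, 0), center, fill)
  .xcorr_shift(reference, rot)
}

#' Stabilize a time-lapse stack by rigid-body registration
#'
#' Aligns every frame to frame 1 by a rigid-body transform (rotation about
#' the nucleus center plus translation), compensating whole-nucleus drift
#' and rotation so that focus displacements reflect focus motion rather
#' than cell motion. The rotation angle is found by a coarse grid search
#' refined with golden-section optimization; at each candidate angle the
#' translation is recovered by FFT cross-correlation.
#'
#' @param stack numeric array `H x W x T`, `T >= 2`.
#' @param nucleus_mask optional logical matrix; its centroid is used as
#'   the rotation center (defaults to the image center).
#' @param max_rotation maximum rotation magnitude searched, degrees.
#' @param rotation_step grid step of the coarse angle search, degrees
#'   (set `max_rotation = 0` to register translation only).
#' @param fill background fill for out-of-frame pixels.
#' @return list with `stack` (stabilized array, same dimensions) and
#'   `transforms` (data.frame per frame: `frame`, `angle_deg`, `dx_px`,
#'   `dy_px`).
#' @export
register_stack <- function(stack, nucleus_mask = NULL,
                           max_rotation = 10, rotation_step = 1,
                           fill = 0) {
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  n_fr <- dim(stack)[3]
  if (n_fr < 2L) stop("need at least 2 frames to register")
  ref <- stack[, , 1]
  if (stats::sd(ref) == 0) {
    warning("reference frame is constant; stack returned unchanged")
    return(list(stack = stack,
                transforms = data.frame(frame = seq_len(n_fr) - 1L,
                                        angle_deg = 0, dx_px = 0, dy_px = 0)))
  }
  center <- if (!is.null(nucleus_mask)) {
    idx <- which(nucleus_mask > 0)
    H <- nrow(ref)
    c(mean((idx - 1L) %/% H), mean((idx - 1L) %% H))
  } else c((ncol(ref) - 1) / 2, (nrow(ref) - 1) / 2)

  out <- stack
  tf <- data.frame(frame = seq_len(n_fr) - 1L, angle_deg = 0,
                   dx_px = 0, dy_px = 0)
  for (t in 2:n_fr) {
    fr <- stack[, , t]
    if (stats::sd(fr) == 0) {
      warning("frame ", t - 1L, " is constant; left unchanged")
      next
    }
    best_angle <- 0
    if (max_rotation > 0) {
      angles <- seq(-max_rotation, max_rotation, by = rotation_step)
      scores <- vapply(angles, function(a)
        .rigid_score(ref, fr, a, center, fill)$score, numeric(1))
      a0 <- angles[which.max(scores)]
      opt <- stats::optimize(function(a)
        .rigid_score(ref, fr, a, center, fill)$score,
        interval = c(a0 - rotation_step, a0 + rotation_step),
        maximum = TRUE, tol = 0.01)
      best_angle <- opt$maximum
      # keep exactly zero when no rotation improves on none
      if (.rigid_score(ref, fr, 0, center, fill)$score >= opt$objective)
        best_angle <- 0
    }
    sc <- .rigid_score(ref, fr, best_angle, center, fill)
    out[, , t] <- transform_rigid(fr, best_angle, sc$shift, center, fill)
    tf$angle_deg[t] <- best_angle
    tf$dx_px[t] <- sc$shift[1]
    tf$dy_px[t] <- sc$shift[2]
  }
  list(stack = out, transforms = tf)
}
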