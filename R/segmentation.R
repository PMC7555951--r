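#' Maximum-intensity projection of a z-stack
#'
#' Collapses a 3-D stack to a 2-D image by taking, at every pixel, the
#' maximum over z-planes. Time-lapse analysis in this package operates on
#' such projections.
#'
#' @param z_stack numeric array `H x W x Z` (or a 2-D matrix, returned
#'   unchanged).
#' @return numeric matrix `H x W`.
#' @export
max_project <- function(z_stack) {
  if (is.matrix(z_stack)) return(z_stack)
  if (!is.array(z_stack) || length(dim(z_stack)) != 3L)
    stop("z_stack must be a 2-D matrix or a 3-D array")
  if (dim(z_stack)[3] < 1L) stop("z_stack has no planes")
  out <- z_stack[, , 1]
  for (k in seq_len(dim(z_stack)[3])[-1]) out <- pmax(out, z_stack[, , k])
  out
}

#' Segment cell nuclei in a fluorescence image
#'
#' Global Otsu threshold on the (optionally smoothed) image, hole filling,
#' connected-component labeling, then removal of components touching the
#' image border and of components below a minimum area. Intended for
#' isolating nuclei from the nuclear fluorescence signal itself.
#'
#' @param image numeric matrix on the 8-bit (0--255) intensity scale.
#' @param min_area minimum nucleus area, pixels.
#' @param exclude_border drop components touching the image border.
#' @param fill_holes fill interior holes before labeling.
#' @param smoothing_sigma Gaussian pre-smoothing sigma in pixels (0 = none).
#' @return integer matrix of nucleus labels (0 = background); may contain
#'   zero labels for a blank image.
#' @export
segment_nuclei <- function(image, min_area = 200, exclude_border = TRUE,
                           fill_holes = TRUE, smoothing_sigma = 1) {
  stopifnot(is.matrix(image))
  img <- image
  if (smoothing_sigma > 0) img <- as.matrix(EBImage::gblur(img, smoothing_sigma))
  rng <- range(img)
  if (diff(rng) <= .Machine$double.eps) return(matrix(0L, nrow(img), ncol(img)))
  thr <- EBImage::otsu(EBImage::Image(img), range = rng)
  bin <- img > thr
  if (fill_holes) bin <- EBImage::fillHull(bin) > 0
  lab <- EBImage::bwlabel(bin)
  lab <- as.matrix(lab)
  if (max(lab) == 0L) return(matrix(0L, nrow(img), ncol(img)))
  keep <- tabulate(lab[lab > 0], nbins = max(lab)) >= min_area
  if (exclude_border) {
    border_labels <- unique(c(lab[1, ], lab[nrow(lab), ],
                              lab[, 1], lab[, ncol(lab)]))
    keep[border_labels[border_labels > 0]] <- FALSE
  }
  relab <- integer(max(lab))
  relab[which(keep)] <- seq_len(sum(keep))
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- relab[lab[nz]]
  out
}

#' Per-frame nuclear intensity statistics
#'
#' Mean and sample standard deviation (n-1 denominator) of pixel
#' intensities inside the nucleus mask: the two frame statistics the
#' adaptive threshold model is built on.
#'
#' @param image numeric matrix.
#' @param nucleus_mask logical matrix (or 0/1) marking nucleus pixels;
#'   must cover at least 2 pixels.
#' @param frame_index 0-based frame index carried into the result.
#' @param sd_type `"sample"` (n-1, default) or `"population"` (n).
#' @return data.frame with `frame`, `mean_intensity`, `sd_intensity`,
#'   `n_pixels`.
#' @export
compute_frame_stats <- function(image, nucleus_mask, frame_index = 0L,
                                sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  v <- image[nucleus_mask > 0]
  if (length(v) < 2L)
    stop("nucleus mask must cover at least 2 pixels (frame ",
         frame_index, ")")
  s <- stats::sd(v)
  if (sd_type == "population") s <- s * sqrt((length(v) - 1) / length(v))
  data.frame(frame = as.integer(frame_index),
             mean_intensity = mean(v), sd_intensity = s,
             n_pixels = length(v))
}

#' Calibrate the adaptive threshold factor from a manual threshold
#'
#' Converts a manually chosen lower intensity threshold on the first frame
#' into a dimensionless factor expressed in units of that frame's nuclear
#' intensity SD:
#' `factor = (manual_lower_threshold - mean_0) / sd_0`.
#' The factor is held constant for every later frame of the same cell,
#' where the frame threshold becomes `mean_t + factor * sd_t`
#' (see [frame_threshold()]), so the threshold tracks bleaching and
#' global intensity changes.
#'
#' @param manual_lower_threshold manually set lower threshold (intensity
#'   units) chosen on the first frame.
#' @param stats0 frame statistics of the calibration frame, from
#'   [compute_frame_stats()].
#' @param upper_threshold fixed upper threshold (255 for 8-bit images).
#' @return list of class `threshold_model` with `factor`,
#'   `manual_lower_threshold`, `upper_threshold`.
#' @export
#' @examples
#' s0 <- data.frame(frame = 0L, mean_intensity = 40, sd_intensity = 20)
#' calibrate_threshold_factor(100, s0)$factor  # 3
calibrate_threshold_factor <- function(manual_lower_threshold, stats0,
                                       upper_threshold = 255) {
  if (!is.finite(stats0$sd_intensity) || stats0$sd_intensity <= 0)
    stop("cannot calibrate: SD of frame ", stats0$frame, " is zero")
  structure(list(
    factor = (manual_lower_threshold - stats0$mean_intensity) /
      stats0$sd_intensity,
    manual_lower_threshold = manual_lower_threshold,
    upper_threshold = upper_threshold
  ), class = "threshold_model")
}

#' Adaptive per-frame threshold
#'
#' Applies a calibrated threshold model to one frame's nuclear intensity
#' statistics: `threshold_t = mean_t + factor * sd_t`. Applied to the
#' calibration frame's own statistics this reproduces the manual lower
#' threshold exactly.
#'
#' @param stats_t frame statistics from [compute_frame_stats()].
#' @param model a `threshold_model` from [calibrate_threshold_factor()].
#' @return numeric threshold (intensity units).
#' @export
frame_threshold <- function(stats_t, model) {
  stopifnot(inherits(model, "threshold_model"))
  stats_t$mean_intensity + model$factor * stats_t$sd_intensity
}

#' Segment foci within a nucleus by adaptive threshold and watershed
#'
#' Binarizes the frame between `threshold` and `upper_threshold`, splits
#' touching blobs along the ridges of the distance transform (watershed),
#' and discards blobs below a minimum area. The Gaussian-smoothed copy of
#' the first frame is used when choosing the manual threshold; frames are
#' segmented unblurred.
#'
#' @param image numeric matrix (one frame).
#' @param threshold lower intensity threshold for this frame.
#' @param upper_threshold upper intensity bound (default 255).
#' @param mask optional logical matrix restricting segmentation (e.g. the
#'   nucleus mask).
#' @param min_area minimum focus area, pixels (default 4; set 0 to keep
#'   every suprathreshold blob).
#' @param watershed_split split touching blobs by distance-transform
#'   watershed (default TRUE).
#' @return integer matrix of focus labels (0 = background).
#' @export
segment_foci <- function(image, threshold, upper_threshold = 255,
                         mask = NULL, min_area = 4, watershed_split = TRUE) {
  stopifnot(is.matrix(image))
  bin <- image >= threshold & image <= upper_threshold
  if (!is.null(mask)) bin <- bin & (mask > 0)
  if (!any(bin)) return(matrix(0L, nrow(image), ncol(image)))
  if (watershed_split) {
    dm <- EBImage::distmap(EBImage::Image(bin * 1))
    lab <- EBImage::watershed(dm, tolerance = 0.5)
  } else {
    lab <- EBImage::bwlabel(bin * 1)
  }
  lab <- as.matrix(lab)
  storage.mode(lab) <- "integer"
  if (min_area > 0 && max(lab) > 0L) {
    keep <- tabulate(lab[lab > 0], nbins = max(lab)) >= min_area
    relab <- integer(max(lab))
    relab[which(keep)] <- seq_len(sum(keep))
    nz <- lab > 0
    lab[nz] <- relab[lab[nz]]
  }
  lab
}

#' Measure segmented foci
#'
#' Per focus label: area (pixel count times `pixel_size^2`), mean pixel
#' intensity, total intensity (mean times area) and the center of mass.
#' The center of mass is the intensity-weighted centroid by default; the
#' unweighted geometric centroid is available via `com_type`. Pixel
#' coordinates are 0-based with origin at the top-left pixel center;
#' reported coordinates are in micrometres.
#'
#' @param label_map integer matrix of focus labels (0 = background).
#' @param image numeric intensity matrix, congruent with `label_map`.
#' @param pixel_size micrometres per pixel.
#' @param frame_index 0-based frame index carried into the result.
#' @param com_type `"intensity"` (weighted, default) or `"geometric"`.
#' @return data.frame, one row per focus: `frame`, `label`, `com_x_um`,
#'   `com_y_um`, `area_um2`, `mean_intensity`, `total_intensity`.
#' @export
measure_foci <- function(label_map, image, pixel_size,
                         frame_index = 0L,
                         com_type = c("intensity", "geometric")) {
  com_type <- match.arg(com_type)
  stopifnot(all(dim(label_map) == dim(image)), pixel_size > 0)
  empty <- data.frame(frame = integer(0), label = integer(0),
                      com_x_um = numeric(0), com_y_um = numeric(0),
                      area_um2 = numeric(0), mean_intensity = numeric(0),
                      total_intensity = numeric(0))
  if (max(label_map) == 0L) return(empty)
  nz <- which(label_map > 0)
  lab <- label_map[nz]
  val <- image[nz]
  H <- nrow(image)
  ypix <- (nz - 1L) %% H          # 0-based row
  xpix <- (nz - 1L) %/% H         # 0-based col
  w <- if (com_type == "intensity") val else rep(1, length(val))
  npix <- tapply(val, lab, length)
  wsum <- tapply(w, lab, sum)
  # guard: all-zero-intensity blob falls back to geometric centroid
  zero_w <- wsum <= 0
  if (any(zero_w)) {
    w[lab %in% as.integer(names(wsum)[zero_w])] <- 1
    wsum <- tapply(w, lab, sum)
  }
  cx <- tapply(w * xpix, lab, sum) / wsum
  cy <- tapply(w * ypix, lab, sum) / wsum
  meanI <- tapply(val, lab, mean)
  area <- as.numeric(npix) * pixel_size^2
  out <- data.frame(frame = as.integer(frame_index),
                    label = as.integer(names(npix)),
                    com_x_um = as.numeric(cx) * pixel_size,
                    com_y_um = as.numeric(cy) * pixel_size,
                    area_um2 = area,
                    mean_intensity = as.numeric(meanI),
                    total_intensity = as.numeric(meanI) * area)
  out[order(out$label), , drop = FALSE]
}
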