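#' Time-averaged mean squared displacement of one track
#'
#' For each lag `n * dt`, the mean squared center-of-mass displacement over
#' all ordered in-track position pairs separated by `n` frames
#' (overlapping windows, the usual time-averaged estimator). Free 2-D
#' diffusion gives `MSD(t) = 4 D t`.
#'
#' @param track matrix or data.frame of consecutive positions: either
#'   columns `com_x_um`/`com_y_um` or a two-column matrix, micrometres.
#' @param frame_interval frame interval, minutes.
#' @param overlapping use all ordered pairs (default); if `FALSE`, only
#'   non-overlapping windows contribute.
#' @return data.frame of class `msd_curve`: `lag_min`, `msd_um2`, `sem`,
#'   `n_pairs`. A single-position track yields zero rows.
#' @export
#' @examples
#' tr <- cbind(c(0, 1, 2), c(0, 0, 0))
#' compute_track_msd(tr, frame_interval = 20)
compute_track_msd <- function(track, frame_interval = 20,
                              overlapping = TRUE) {
  pos <- if (is.data.frame(track))
    cbind(track$com_x_um, track$com_y_um) else as.matrix(track)
  n <- nrow(pos)
  out <- data.frame(lag_min = numeric(0), msd_um2 = numeric(0),
                    sem = numeric(0), n_pairs = integer(0))
  class(out) <- c("msd_curve", "data.frame")
  if (n < 2L) return(out)
  rows <- vector("list", n - 1L)
  for (lag in seq_len(n - 1L)) {
    i <- if (overlapping) seq_len(n - lag) else seq(1L, n - lag, by = lag)
    sq <- (pos[i + lag, 1] - pos[i, 1])^2 + (pos[i + lag, 2] - pos[i, 2])^2
    rows[[lag]] <- data.frame(
      lag_min = lag * frame_interval, msd_um2 = mean(sq),
      sem = if (length(sq) > 1) stats::sd(sq) / sqrt(length(sq)) else NA_real_,
      n_pairs = length(sq))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Ensemble mean squared displacement across tracks
#'
#' Per-lag unweighted mean of the per-track time-averaged MSD values over
#' all tracks possessing that lag, with the standard error across tracks.
#' The curve is truncated at the largest lag supported by at least
#' `min_tracks` tracks.
#'
#' @param tracks list of tracks (each a position matrix or data.frame as
#'   for [compute_track_msd()]), or the long table from [build_tracks()]
#'   (split on `track_id`).
#' @param frame_interval frame interval, minutes.
#' @param min_tracks minimum number of contributing tracks per reported
#'   lag (default 3).
#' @return `msd_curve` data.frame: `lag_min`, `msd_um2`, `sem`,
#'   `n_tracks`.
#' @export
ensemble_msd <- function(tracks, frame_interval = 20, min_tracks = 3L) {
  if (is.data.frame(tracks)) tracks <- split(tracks, tracks$track_id)
  if (length(tracks) == 0L) {
    warning("no tracks supplied; empty MSD curve")
    out <- data.frame(lag_min = numeric(0), msd_um2 = numeric(0),
                      sem = numeric(0), n_tracks = integer(0))
    class(out) <- c("msd_curve", "data.frame")
    return(out)
  }
  curves <- lapply(tracks, compute_track_msd, frame_interval = frame_interval)
  curves <- curves[vapply(curves, nrow, integer(1)) > 0]
  if (length(curves) == 0L) {
    warning("no track has >= 2 positions; empty MSD curve")
    out <- data.frame(lag_min = numeric(0), msd_um2 = numeric(0),
                      sem = numeric(0), n_tracks = integer(0))
    class(out) <- c("msd_curve", "data.frame")
    return(out)
  }
  all_lags <- sort(unique(unlist(lapply(curves, `[[`, "lag_min"))))
  rows <- lapply(all_lags, function(L) {
    vals <- unlist(lapply(curves, function(cv) cv$msd_um2[cv$lag_min == L]))
    data.frame(lag_min = L, msd_um2 = mean(vals),
               sem = if (length(vals) > 1)
                 stats::sd(vals) / sqrt(length(vals)) else NA_real_,
               n_tracks = length(vals))
  })
  out <- do.call(rbind, rows)
  keep_min <- min(min_tracks, max(out$n_tracks))
  out <- out[out$n_tracks >= keep_min, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Fit an apparent diffusion coefficient to an MSD curve
#'
#' Unweighted least-squares line through the origin, `MSD = a * t`, fitted
#' on the first `n_points` nonzero lags (lag 0 is identically zero and
#' excluded; the fit is anchored at the origin). For 2-D diffusion
#' `a = 4 D`, so `D = a / 4`.
#'
#' @param curve an `msd_curve` data.frame.
#' @param n_points number of initial nonzero-lag points fitted (default 4,
#'   fewer if the curve is shorter).
#' @param weighted if `TRUE`, weight points by `1/sem^2`.
#' @return list of class `diffusion_fit`: `slope` (um^2/min),
#'   `D` (um^2/min), `n_points`, `residual_norm`.
#' @export
fit_diffusion_coefficient <- function(curve, n_points = 4L,
                                      weighted = FALSE) {
  cv <- curve[curve$lag_min > 0, , drop = FALSE]
  if (nrow(cv) < 2L) stop("need at least 2 nonzero-lag MSD points to fit")
  cv <- cv[order(cv$lag_min), , drop = FALSE]
  cv <- cv[seq_len(min(n_points, nrow(cv))), , drop = FALSE]
  w <- if (weighted && all(is.finite(cv$sem)) && all(cv$sem > 0))
    1 / cv$sem^2 else rep(1, nrow(cv))
  a <- sum(w * cv$lag_min * cv$msd_um2) / sum(w * cv$lag_min^2)
  res <- cv$msd_um2 - a * cv$lag_min
  structure(list(slope = a, D = a / 4, n_points = nrow(cv),
                 residual_norm = sqrt(sum(w * res^2))),
            class = "diffusion_fit")
}

#' Per-frame focus intensity, area and total-amount time series
#'
#' For every frame, the mean over foci of the focus mean intensity, the
#' focus area, and the total amount of signal per focus (mean intensity
#' times area), each with its standard error. Frames with no foci report
#' missing values, not zeros.
#'
#' @param foci data.frame of measured foci across frames (needs `frame`,
#'   `mean_intensity`, `area_um2`, `total_intensity`).
#' @param n_frames total frame count; defaults to `max(frame) + 1`.
#' @return data.frame per frame: `frame`, `n_foci`, `mean_intensity`,
#'   `sem_intensity`, `mean_area_um2`, `sem_area`, `mean_total`,
#'   `sem_total`.
#' @export
focus_timeseries <- function(foci, n_frames = NULL) {
  if (is.null(n_frames))
    n_frames <- if (nrow(foci)) max(foci$frame) + 1L else 0L
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  rows <- lapply(0:(n_frames - 1L), function(t) {
    g <- foci[foci$frame == t, , drop = FALSE]
    if (nrow(g) == 0)
      return(data.frame(frame = t, n_foci = 0L,
                        mean_intensity = NA_real_, sem_intensity = NA_real_,
                        mean_area_um2 = NA_real_, sem_area = NA_real_,
                        mean_total = NA_real_, sem_total = NA_real_))
    data.frame(frame = t, n_foci = nrow(g),
               mean_intensity = mean(g$mean_intensity),
               sem_intensity = sem(g$mean_intensity),
               mean_area_um2 = mean(g$area_um2),
               sem_area = sem(g$area_um2),
               mean_total = mean(g$total_intensity),
               sem_total = sem(g$total_intensity))
  })
  do.call(rbind, rows)
}

#' Histogram-anchored kernel density estimate
#'
#' Gaussian-kernel density with a fixed bandwidth (the kernel SD in data
#' units), rescaled so the area under the curve equals the area of the
#' source histogram. A peak-normalization factor can be computed at the
#' first time point (making the highest histogram peak equal 1) and the
#' same factor applied to every later distribution; two conditions can be
#' compared by scaling their histogram areas to be equal first.
#'
#' @param values numeric sample (length >= 2).
#' @param bandwidth Gaussian kernel SD in data units (> 0). Conventional
#'   values for focus summaries: 6 for per-focus signal intensity, 0.3 for
#'   focus area, 220 for total signal per focus.
#' @param breaks histogram breaks (passed to [hist()]); the histogram
#'   defines the target area.
#' @param normalization_factor multiplicative factor from a reference
#'   (first time point) distribution; computed here when `NULL`.
#' @param target_area if given, the histogram area is rescaled to this
#'   value before anchoring (used to put two conditions on equal areas).
#' @param n_grid evaluation grid size.
#' @return list of class `density_curve`: `x`, `y`, `bandwidth`,
#'   `histogram_area`, `normalization_factor`, `n`.
#' @export
kde_distribution <- function(values, bandwidth, breaks = "Sturges",
                             normalization_factor = NULL,
                             target_area = NULL, n_grid = 512) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (!is.numeric(bandwidth) || bandwidth <= 0)
    stop("bandwidth must be positive")
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  hist_area <- sum(h$counts * diff(h$breaks))
  area_scale <- if (is.null(target_area)) 1 else target_area / hist_area
  eff_area <- hist_area * area_scale
  # grid must resolve the kernel: >= 8 points per bandwidth, tails to 4 SD
  span <- diff(range(values)) + 8 * bandwidth
  n_grid <- max(n_grid, min(2^15, 2^ceiling(log2(span / bandwidth * 8))))
  d <- stats::density(values, bw = bandwidth, kernel = "gaussian",
                      n = n_grid,
                      from = min(values) - 4 * bandwidth,
                      to = max(values) + 4 * bandwidth)
  # density integrates to 1; scale the curve to the histogram area
  y <- d$y * eff_area
  if (is.null(normalization_factor))
    normalization_factor <- 1 / (max(h$counts * area_scale))
  y <- y * normalization_factor
  structure(list(x = d$x, y = y, bandwidth = bandwidth,
                 histogram_area = eff_area,
                 normalization_factor = normalization_factor,
                 n = length(values)),
            class = "density_curve")
}

#' Area under a density curve
#'
#' Trapezoidal integral of a [kde_distribution()] curve, with the peak
#' normalization undone so the result is comparable to the source
#' histogram area.
#'
#' @param curve a `density_curve`.
#' @param normalized if `TRUE`, integrate the curve as emitted (including
#'   the peak-normalization factor).
#' @return numeric area.
#' @export
density_curve_area <- function(curve, normalized = FALSE) {
  y <- curve$y
  if (!normalized) y <- y / curve$normalization_factor
  sum(diff(curve$x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Classify an MSD curve as linear (free diffusion) or saturating
#' (confined motion)
#'
#' Compares a through-origin line `MSD = a t` against a single-exponential
#' plateau `MSD = c (1 - exp(-t / tau))` by residual norm. Free diffusion
#' gives a straight MSD line; confinement bends the curve toward a
#' plateau bounded by the confinement geometry.
#'
#' @param curve an `msd_curve` with at least 6 nonzero-lag points
#'   (shorter curves return `"indeterminate"`).
#' @param ratio_threshold the saturating model must reduce the residual
#'   norm by at least this factor to win (guards against preferring the
#'   2-parameter model on noise alone).
#' @param weighted weight residuals by `1/sem^2` when per-lag SEMs are
#'   available (default), so poorly estimated long lags do not dominate
#'   the comparison.
#' @return list: `shape` (`"linear"`, `"saturating"` or
#'   `"indeterminate"`), `residual_linear`, `residual_saturating`,
#'   `ratio`, `plateau` (NA for linear).
#' @export
classify_msd_shape <- function(curve, ratio_threshold = 0.6,
                               weighted = TRUE) {
  cv <- curve[curve$lag_min > 0, , drop = FALSE]
  if (nrow(cv) < 6L)
    return(list(shape = "indeterminate", residual_linear = NA_real_,
                residual_saturating = NA_real_, ratio = NA_real_,
                plateau = NA_real_))
  t <- cv$lag_min; y <- cv$msd_um2
  w <- if (weighted && !is.null(cv$sem) && all(is.finite(cv$sem)) &&
           all(cv$sem > 0)) 1 / cv$sem^2 else rep(1, length(t))
  a <- sum(w * t * y) / sum(w * t^2)
  res_lin <- sqrt(sum(w * (y - a * t)^2))
  # an (essentially) exact line: the saturating model can only mimic it
  if (res_lin <= 1e-10 * max(abs(y), 1e-12))
    return(list(shape = "linear", residual_linear = res_lin,
                residual_saturating = NA_real_, ratio = NA_real_,
                plateau = NA_real_))
  # plateau fit: grid over tau, closed-form c given tau
  # tau is capped at the largest observed lag: as tau -> Inf the plateau
  # model degenerates into a straight line, so a "plateau" beyond the
  # data window is not evidence of confinement
  tau_grid <- exp(seq(log(min(t) / 4), log(max(t)), length.out = 60))
  best <- Inf; best_c <- NA_real_; best_tau <- NA_real_
  for (tau in tau_grid) {
    b <- 1 - exp(-t / tau)
    cc <- sum(w * b * y) / sum(w * b^2)
    r <- sum(w * (y - cc * b)^2)
    if (r < best) { best <- r; best_c <- cc; best_tau <- tau }
  }
  # refine tau locally, within the identifiable range
  opt <- stats::optimize(function(tau) {
    b <- 1 - exp(-t / tau)
    cc <- sum(w * b * y) / sum(w * b^2)
    sum(w * (y - cc * b)^2)
  }, interval = c(best_tau / 3, min(best_tau * 3, max(t))))
  if (opt$objective < best) {
    best <- opt$objective
    b <- 1 - exp(-t / opt$minimum)
    best_c <- sum(w * b * y) / sum(w * b^2)
  }
  res_sat <- sqrt(best)
  ratio <- res_sat / res_lin
  list(shape = if (ratio < ratio_threshold) "saturating" else "linear",
       residual_linear = res_lin, residual_saturating = res_sat,
       ratio = ratio, plateau = best_c)
}
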