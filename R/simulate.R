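#' Simulation configuration for synthetic focus time-lapse stacks
#'
#' Bundles every parameter of the synthetic time-lapse generator into a
#' validated configuration object. Defaults emulate a confocal live-cell
#' acquisition of a single nucleus imaged every 20 minutes: point-spread
#' blurred repair foci diffusing inside an elliptical nucleus, with optional
#' focus birth/death, intensity growth, photobleaching, whole-nucleus
#' drift/rotation and detector noise.
#'
#' Intensities are on the 8-bit scale (0--255) that the adaptive threshold of
#' [calibrate_threshold_factor()] assumes. The nucleus background is strictly
#' positive so per-frame intensity statistics are always defined.
#'
#' @param image_size integer(2), image height and width in pixels.
#' @param n_frames number of time frames.
#' @param frame_interval time between frames, minutes.
#' @param pixel_size pixel edge length, micrometres per pixel.
#' @param nucleus_center ellipse center `(x, y)` in pixel units (0-based).
#' @param nucleus_axes ellipse semi-axes `(a, b)` in pixels.
#' @param nucleus_background nucleus interior intensity (8-bit units).
#' @param nucleus_drift per-frame rigid translation `(dx, dy)` in pixels.
#' @param nucleus_rotation per-frame rigid rotation, degrees (about the
#'   nucleus center).
#' @param n_initial_foci number of foci alive in frame 0.
#' @param min_initial_spacing minimum pairwise distance (micrometres)
#'   enforced when placing foci; 0 disables the constraint. Use this to
#'   realize low-density conditions (e.g. nearest-neighbour spacing well
#'   above the expected diffusion step) by construction.
#' @param birth_rate expected new foci per frame (Poisson).
#' @param death_prob per-focus, per-frame disappearance probability.
#' @param diffusion_coefficient focus diffusion coefficient, um^2/min.
#' @param confinement_radius confinement disc radius in micrometres, or
#'   `Inf` for unconfined motion.
#' @param focus_sigma Gaussian point-spread width of a rendered focus, pixels.
#' @param focus_amplitude peak intensity of a focus above background at
#'   frame 0 (8-bit units).
#' @param amplitude_growth fractional per-frame growth of focus amplitude.
#' @param bleach_rate fractional per-frame decay applied to the whole signal.
#' @param noise_poisson_scale scale of Poisson shot noise (photons per
#'   intensity unit); 0 disables shot noise.
#' @param noise_gaussian_sd standard deviation of additive Gaussian read
#'   noise (8-bit units); 0 disables read noise.
#' @param seed integer seed; identical config and seed give bit-identical
#'   stacks and ground truth.
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_timelapse()], [simulate_two_channel()]
#' @export
#' @examples
#' cfg <- sim_config(n_frames = 5, n_initial_foci = 3, seed = 1)
#' sim <- simulate_timelapse(cfg)
#' dim(sim$stack)
sim_config <- function(image_size = c(128L, 128L),
                       n_frames = 51L,
                       frame_interval = 20,
                       pixel_size = 0.1,
                       nucleus_center = NULL,
                       nucleus_axes = NULL,
                       nucleus_background = 40,
                       nucleus_drift = c(0, 0),
                       nucleus_rotation = 0,
                       n_initial_foci = 8L,
                       min_initial_spacing = 0,
                       birth_rate = 0,
                       death_prob = 0,
                       diffusion_coefficient = 0.005,
                       confinement_radius = Inf,
                       focus_sigma = 1.5,
                       focus_amplitude = 120,
                       amplitude_growth = 0,
                       bleach_rate = 0,
                       noise_poisson_scale = 0,
                       noise_gaussian_sd = 2,
                       seed = 1L) {
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 8L))
    stop("image_size must be two integers >= 8")
  if (is.null(nucleus_center))
    nucleus_center <- (rev(image_size) - 1) / 2   # (x, y)
  if (is.null(nucleus_axes))
    nucleus_axes <- rev(image_size) * 0.35
  stopifnot(n_frames >= 1, frame_interval > 0, pixel_size > 0,
            length(nucleus_drift) == 2, length(nucleus_center) == 2,
            length(nucleus_axes) == 2, nucleus_background > 0,
            n_initial_foci >= 0, focus_sigma > 0, focus_amplitude >= 0,
            noise_poisson_scale >= 0, noise_gaussian_sd >= 0)
  if (diffusion_coefficient < 0)
    stop("diffusion_coefficient must be >= 0")
  if (birth_rate < 0) stop("birth_rate must be >= 0")
  if (death_prob < 0 || death_prob > 1)
    stop("death_prob must be a probability in [0, 1]")
  if (!(bleach_rate >= 0 && bleach_rate < 1))
    stop("bleach_rate must lie in [0, 1)")
  if (confinement_radius <= 0)
    stop("confinement_radius must be positive (use Inf for unconfined)")
  # the nucleus (plus drift over the run) must fit inside the image
  total_drift <- abs(nucleus_drift) * (n_frames - 1)
  if (nucleus_center[1] + nucleus_axes[1] + total_drift[1] >= image_size[2] ||
      nucleus_center[2] + nucleus_axes[2] + total_drift[2] >= image_size[1] ||
      nucleus_center[1] - nucleus_axes[1] - total_drift[1] < 0 ||
      nucleus_center[2] - nucleus_axes[2] - total_drift[2] < 0)
    stop("nucleus (including drift) does not fit inside the image")
  structure(list(
    image_size = image_size, n_frames = as.integer(n_frames),
    frame_interval = frame_interval, pixel_size = pixel_size,
    nucleus_center = as.numeric(nucleus_center),
    nucleus_axes = as.numeric(nucleus_axes),
    nucleus_background = nucleus_background,
    nucleus_drift = as.numeric(nucleus_drift),
    nucleus_rotation = nucleus_rotation,
    n_initial_foci = as.integer(n_initial_foci),
    min_initial_spacing = min_initial_spacing,
    birth_rate = birth_rate, death_prob = death_prob,
    diffusion_coefficient = diffusion_coefficient,
    confinement_radius = confinement_radius,
    focus_sigma = focus_sigma, focus_amplitude = focus_amplitude,
    amplitude_growth = amplitude_growth, bleach_rate = bleach_rate,
    noise_poisson_scale = noise_poisson_scale,
    noise_gaussian_sd = noise_gaussian_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a single Brownian (optionally confined) focus trajectory
#'
#' Draws a 2-D random walk whose per-axis increments have variance
#' `2 * D * dt`, so that the expected mean squared displacement of free
#' motion is `4 * D * dt` per lag -- the 2-D diffusion law the MSD analysis
#' assumes. With a finite `confinement_radius`, steps leaving the disc of
#' that radius (centered on the start position) are reflected back across
#' the boundary, producing the saturating MSD of confined motion.
#'
#' @param D diffusion coefficient, um^2/min; must be >= 0.
#' @param n_steps number of positions in the track (>= 1).
#' @param dt time step, minutes.
#' @param confinement_radius disc radius in micrometres, or `Inf`.
#' @param start numeric(2) start position in micrometres.
#' @return An `n_steps` x 2 matrix of positions (columns `x`, `y`, um).
#' @export
#' @examples
#' tr <- simulate_brownian_track(0.005, n_steps = 10, dt = 20)
simulate_brownian_track <- function(D, n_steps, dt,
                                    confinement_radius = Inf,
                                    start = c(0, 0)) {
  if (D < 0) stop("diffusion coefficient D must be >= 0")
  if (dt <= 0) stop("time step dt must be > 0")
  if (n_steps < 1) stop("n_steps must be >= 1")
  n_steps <- as.integer(n_steps)
  pos <- matrix(0, n_steps, 2, dimnames = list(NULL, c("x", "y")))
  pos[1, ] <- start
  if (n_steps == 1L) return(pos)
  sd_step <- sqrt(2 * D * dt)
  steps <- matrix(stats::rnorm(2L * (n_steps - 1L), 0, sd_step),
                  n_steps - 1L, 2L)
  if (is.infinite(confinement_radius)) {
    cum <- rbind(cumsum(steps[, 1]), cumsum(steps[, 2]))
    pos[-1L, ] <- t(cum + start)
  } else {
    center <- start
    cur <- start
    for (i in seq_len(n_steps - 1L)) {
      cur <- cur + steps[i, ]
      cur <- .reflect_into_disc(cur, center, confinement_radius)
      pos[i + 1L, ] <- cur
    }
  }
  pos
}

# Radial reflection at the boundary of a disc; repeated until inside
# (large steps may need more than one reflection).
.reflect_into_disc <- function(p, center, radius) {
  for (k in 1:8) {
    r <- sqrt(sum((p - center)^2))
    if (r <= radius) return(p)
    p <- center + (p - center) * (2 * radius - r) / r
    # if 2*radius - r went negative the point flipped through the center;
    # loop handles it
    if (sqrt(sum((p - center)^2)) <= radius) return(p)
  }
  # pathological step far beyond the disc: clamp to the boundary
  r <- sqrt(sum((p - center)^2))
  center + (p - center) * radius / r
}

# Uniform draw inside an ellipse (rejection-free, via disc mapping).
.runif_ellipse <- function(n, center, axes) {
  u <- sqrt(stats::runif(n))
  th <- stats::runif(n, 0, 2 * pi)
  cbind(center[1] + axes[1] * u * cos(th),
        center[2] + axes[2] * u * sin(th))
}

#' Simulate a seeded synthetic focus time-lapse with ground truth
#'
#' Generates a multi-frame image stack of one nucleus containing
#' point-spread-blurred foci undergoing Brownian (optionally confined)
#' motion, together with a per-frame ground-truth table. Foci are born by a
#' Poisson process, die by per-frame Bernoulli trials, grow in amplitude,
#' bleach globally, and ride along with any rigid nucleus drift/rotation.
#' Rendering happens in the projected 2-D plane (the analysis operates on
#' maximum-intensity projections, so the generator works there directly).
#'
#' @param config a [sim_config()] object.
#' @return A list with elements
#'   \describe{
#'     \item{stack}{numeric array `H x W x n_frames`, 8-bit intensity scale.}
#'     \item{truth}{data.frame, one row per alive focus per frame:
#'       `frame` (0-based), `focus_id`, `x_um`, `y_um`, `amplitude`.}
#'     \item{lineage}{data.frame per focus: `focus_id`, `birth_frame`,
#'       `death_frame` (last alive frame, 0-based).}
#'     \item{nucleus_mask}{logical matrix of the frame-0 nucleus footprint.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
simulate_timelapse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)
  H <- cf$image_size[1]; W <- cf$image_size[2]
  px <- cf$pixel_size
  n_fr <- cf$n_frames

  # Foci live in the co-moving nucleus frame (relative to nucleus center,
  # in um); rigid drift/rotation maps them into image coordinates per frame.
  axes_um <- cf$nucleus_axes * px
  # keep foci off the very rim so their footprint stays inside the nucleus
  margin <- 3 * cf$focus_sigma * px
  place_axes <- pmax(axes_um - margin, 0.25 * axes_um)

  new_focus_pos <- function(n) {
    if (n == 0) return(matrix(numeric(0), 0, 2))
    if (cf$min_initial_spacing <= 0)
      return(.runif_ellipse(n, c(0, 0), place_axes))
    # rejection sampling against already-placed live foci and each other
    placed <- matrix(numeric(0), 0, 2)
    existing <- alive_pos
    for (k in seq_len(n)) {
      ok <- FALSE
      for (try in 1:2000) {
        cand <- as.numeric(.runif_ellipse(1, c(0, 0), place_axes))
        others <- rbind(existing, placed)
        if (nrow(others) == 0 ||
            min(sqrt(rowSums(sweep(others, 2, cand)^2))) >=
              cf$min_initial_spacing) { ok <- TRUE; break }
      }
      if (!ok) stop("cannot place foci at min_initial_spacing = ",
                    cf$min_initial_spacing,
                    " um; reduce the spacing or the focus count")
      placed <- rbind(placed, cand)
    }
    placed
  }

  next_id <- 1L
  alive_ids <- integer(0)
  alive_pos <- matrix(numeric(0), 0, 2)   # nucleus-frame um
  conf_center <- matrix(numeric(0), 0, 2) # per-focus confinement anchor
  birth <- integer(0); death <- integer(0)

  spawn <- function(n, frame) {
    if (n == 0) return(invisible())
    ids <- next_id:(next_id + n - 1L)
    next_id <<- next_id + n
    alive_ids <<- c(alive_ids, ids)
    p <- new_focus_pos(n)
    alive_pos <<- rbind(alive_pos, p)
    conf_center <<- rbind(conf_center, p)
    birth[ids] <<- frame
    death[ids] <<- NA_integer_
  }
  spawn(cf$n_initial_foci, 0L)

  sd_step <- sqrt(2 * cf$diffusion_coefficient * cf$frame_interval)
  truth_rows <- vector("list", n_fr)
  stack <- array(0, c(H, W, n_fr))

  xs <- matrix(rep(0:(W - 1), each = H), H, W)   # x index per pixel
  ys <- matrix(rep(0:(H - 1), W), H, W)          # y index per pixel

  nucleus_mask0 <- NULL
  for (t in seq_len(n_fr) - 1L) {
    if (t > 0L) {
      # deaths
      if (cf$death_prob > 0 && length(alive_ids)) {
        dies <- stats::runif(length(alive_ids)) < cf$death_prob
        death[alive_ids[dies]] <- t - 1L
        alive_ids <- alive_ids[!dies]
        alive_pos <- alive_pos[!dies, , drop = FALSE]
        conf_center <- conf_center[!dies, , drop = FALSE]
      }
      # diffusion in the nucleus frame, confined about each focus' birth spot
      if (length(alive_ids) && sd_step > 0) {
        step <- matrix(stats::rnorm(2L * length(alive_ids), 0, sd_step),
                       ncol = 2)
        newp <- alive_pos + step
        if (is.finite(cf$confinement_radius)) {
          for (i in seq_len(nrow(newp)))
            newp[i, ] <- .reflect_into_disc(newp[i, ], conf_center[i, ],
                                            cf$confinement_radius)
        }
        alive_pos <- newp
      }
      # births
      if (cf$birth_rate > 0) spawn(stats::rpois(1, cf$birth_rate), t)
    }

    # rigid nucleus motion at frame t
    ncenter_px <- cf$nucleus_center + t * cf$nucleus_drift       # (x, y) px
    angle <- t * cf$nucleus_rotation * pi / 180
    R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)

    # image-frame truth positions (um)
    if (length(alive_ids)) {
      img_pos <- t(R %*% t(alive_pos)) +
        matrix(ncenter_px * px, nrow(alive_pos), 2, byrow = TRUE)
    } else img_pos <- matrix(numeric(0), 0, 2)

    amp_t <- cf$focus_amplitude * (1 + cf$amplitude_growth)^t
    bleach_t <- (1 - cf$bleach_rate)^t

    # render nucleus interior (rotated-ellipse membership)
    dx <- (xs - ncenter_px[1]); dy <- (ys - ncenter_px[2])
    ux <- (dx * cos(-angle) - dy * sin(-angle)) / cf$nucleus_axes[1]
    uy <- (dx * sin(-angle) + dy * cos(-angle)) / cf$nucleus_axes[2]
    inside <- (ux^2 + uy^2) <= 1
    frame_img <- matrix(0, H, W)
    frame_img[inside] <- cf$nucleus_background
    if (t == 0L) nucleus_mask0 <- inside

    # render foci as isotropic Gaussians (amplitude above background)
    if (nrow(img_pos)) {
      s2 <- cf$focus_sigma^2
      for (i in seq_len(nrow(img_pos))) {
        cx <- img_pos[i, 1] / px; cy <- img_pos[i, 2] / px
        x0 <- max(0L, floor(cx - 5 * cf$focus_sigma))
        x1 <- min(W - 1L, ceiling(cx + 5 * cf$focus_sigma))
        y0 <- max(0L, floor(cy - 5 * cf$focus_sigma))
        y1 <- min(H - 1L, ceiling(cy + 5 * cf$focus_sigma))
        if (x1 < x0 || y1 < y0) next
        gx <- exp(-((x0:x1) - cx)^2 / (2 * s2))
        gy <- exp(-((y0:y1) - cy)^2 / (2 * s2))
        patch <- amp_t * outer(gy, gx)
        rows <- (y0:y1) + 1L; cols <- (x0:x1) + 1L
        frame_img[rows, cols] <- frame_img[rows, cols] + patch
      }
    }
    frame_img <- frame_img * bleach_t

    # detector noise
    if (cf$noise_poisson_scale > 0) {
      lam <- pmax(frame_img, 0) * cf$noise_poisson_scale
      frame_img <- matrix(stats::rpois(length(lam), lam),
                          H, W) / cf$noise_poisson_scale
    }
    if (cf$noise_gaussian_sd > 0)
      frame_img <- frame_img +
        matrix(stats::rnorm(H * W, 0, cf$noise_gaussian_sd), H, W)
    stack[, , t + 1L] <- pmin(pmax(frame_img, 0), 255)

    if (length(alive_ids)) {
      o <- order(alive_ids)
      truth_rows[[t + 1L]] <- data.frame(
        frame = t, focus_id = alive_ids[o],
        x_um = img_pos[o, 1], y_um = img_pos[o, 2],
        amplitude = amp_t * bleach_t)
    }
  }
  death[alive_ids] <- n_fr - 1L

  truth <- do.call(rbind, truth_rows)
  if (is.null(truth))
    truth <- data.frame(frame = integer(0), focus_id = integer(0),
                        x_um = numeric(0), y_um = numeric(0),
                        amplitude = numeric(0))
  ids <- seq_len(next_id - 1L)
  lineage <- data.frame(focus_id = ids,
                        birth_frame = birth[ids],
                        death_frame = death[ids])
  list(stack = stack, truth = truth, lineage = lineage,
       nucleus_mask = nucleus_mask0, config = cf)
}

#' Simulate fixed-cell two-channel images with nested foci
#'
#' Builds a synthetic fixed-cell field of view for colocalization analysis:
#' channel A carries large repair foci (53BP1-like), channel B carries
#' smaller foci (RPA-like) rendered strictly inside their parent A focus,
#' and an S-phase marker channel (EdU-like) separates bright from dim
#' nuclei. The number of B foci nested in each A focus is drawn from a
#' user-supplied distribution, and the truth records every draw.
#'
#' @param n_cells number of nuclei, laid out on a grid.
#' @param foci_per_cell number of A foci rendered in each nucleus.
#' @param nested_counts_distribution named numeric vector of probabilities
#'   for 0, 1, 2, ... nested B foci per A focus (names are the counts);
#'   must sum to 1.
#' @param edu_positive_fraction fraction of nuclei made EdU-bright.
#' @param seed integer seed.
#' @param cell_size pixel edge of the square tile holding one nucleus.
#' @param pixel_size micrometres per pixel.
#' @param a_sigma,b_sigma Gaussian widths (px) of A and B foci; `b_sigma`
#'   must be smaller than `a_sigma`.
#' @param a_amplitude,b_amplitude peak intensities (8-bit units).
#' @param background nucleus interior intensity in both focus channels.
#' @param noise_gaussian_sd additive read-noise SD; 0 for noise-free images.
#' @return list with `channel_a`, `channel_b`, `edu` (matrices),
#'   `truth` (per A focus: `cell`, `a_focus_id`, `x_um`, `y_um`,
#'   `n_nested`), `cells` (per cell: `cell`, `edu_positive`),
#'   `nucleus_labels` (integer matrix of true nucleus footprints),
#'   and `pixel_size`.
#' @export
simulate_two_channel <- function(n_cells,
                                 foci_per_cell,
                                 nested_counts_distribution = c(`0` = 0.6, `1` = 0.3, `2` = 0.1),
                                 edu_positive_fraction = 1,
                                 seed = 1L,
                                 cell_size = 100L,
                                 pixel_size = 0.1,
                                 a_sigma = 2.5,
                                 b_sigma = 1.0,
                                 a_amplitude = 150,
                                 b_amplitude = 150,
                                 background = 30,
                                 noise_gaussian_sd = 0) {
  stopifnot(n_cells >= 1, foci_per_cell >= 0, pixel_size > 0)
  p <- nested_counts_distribution
  if (abs(sum(p) - 1) > 1e-8)
    stop("nested_counts_distribution probabilities must sum to 1")
  counts_support <- as.integer(names(p))
  if (anyNA(counts_support) || any(counts_support < 0))
    stop("nested_counts_distribution names must be nonnegative counts")
  if (b_sigma >= a_sigma)
    stop("nested B foci must be smaller than their parent A focus ",
         "(b_sigma < a_sigma)")
  set.seed(seed)

  ncol_grid <- ceiling(sqrt(n_cells))
  nrow_grid <- ceiling(n_cells / ncol_grid)
  H <- nrow_grid * cell_size; W <- ncol_grid * cell_size
  chA <- matrix(0, H, W); chB <- matrix(0, H, W); edu <- matrix(0, H, W)
  nuc_lab <- matrix(0L, H, W)

  nuc_r <- cell_size * 0.38
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)

  render <- function(img, cx, cy, sigma, amp) {
    x0 <- max(0L, floor(cx - 5 * sigma)); x1 <- min(W - 1L, ceiling(cx + 5 * sigma))
    y0 <- max(0L, floor(cy - 5 * sigma)); y1 <- min(H - 1L, ceiling(cy + 5 * sigma))
    gx <- exp(-((x0:x1) - cx)^2 / (2 * sigma^2))
    gy <- exp(-((y0:y1) - cy)^2 / (2 * sigma^2))
    img[(y0:y1) + 1L, (x0:x1) + 1L] <-
      img[(y0:y1) + 1L, (x0:x1) + 1L] + amp * outer(gy, gx)
    img
  }

  edu_pos <- rep(FALSE, n_cells)
  n_bright <- round(edu_positive_fraction * n_cells)
  if (n_bright > 0) edu_pos[sample.int(n_cells, n_bright)] <- TRUE

  truth_rows <- vector("list", n_cells)
  aid <- 0L
  for (cell in seq_len(n_cells)) {
    gi <- (cell - 1L) %/% ncol_grid; gj <- (cell - 1L) %% ncol_grid
    cx0 <- gj * cell_size + (cell_size - 1) / 2
    cy0 <- gi * cell_size + (cell_size - 1) / 2
    inside <- ((xs - cx0)^2 + (ys - cy0)^2) <= nuc_r^2
    chA[inside] <- background
    chB[inside] <- background
    nuc_lab[inside] <- cell
    edu[inside] <- if (edu_pos[cell]) 180 else 20

    if (foci_per_cell > 0) {
      # A foci placed with a minimum spacing so they segment as one blob each
      placed <- matrix(numeric(0), 0, 2)
      min_d <- 4 * a_sigma
      tries <- 0L
      while (nrow(placed) < foci_per_cell && tries < 4000L) {
        tries <- tries + 1L
        u <- sqrt(stats::runif(1)); th <- stats::runif(1, 0, 2 * pi)
        cand <- c(cx0 + (nuc_r - 4 * a_sigma) * u * cos(th),
                  cy0 + (nuc_r - 4 * a_sigma) * u * sin(th))
        if (nrow(placed) == 0 ||
            min(sqrt(rowSums(sweep(placed, 2, cand)^2))) >= min_d)
          placed <- rbind(placed, cand)
      }
      if (nrow(placed) < foci_per_cell)
        stop("could not place ", foci_per_cell,
             " A foci with the required spacing; reduce foci_per_cell")
      nested <- sample(counts_support, nrow(placed), replace = TRUE, prob = p)
      for (i in seq_len(nrow(placed))) {
        aid <- aid + 1L
        chA <- render(chA, placed[i, 1], placed[i, 2], a_sigma, a_amplitude)
        # B foci strictly inside the parent A footprint; siblings are put
        # on a ring with evenly spaced angles so they remain resolvable
        # at the rendering resolution
        if (nested[i] == 1L) {
          off_r <- stats::runif(1, 0, max(a_sigma - b_sigma, 0.5))
          off_t <- stats::runif(1, 0, 2 * pi)
          chB <- render(chB, placed[i, 1] + off_r * cos(off_t),
                        placed[i, 2] + off_r * sin(off_t),
                        b_sigma, b_amplitude)
        } else if (nested[i] >= 2L) {
          ring <- a_sigma * 0.9
          th0 <- stats::runif(1, 0, 2 * pi)
          for (k in seq_len(nested[i])) {
            th_k <- th0 + (k - 1) * 2 * pi / nested[i]
            chB <- render(chB, placed[i, 1] + ring * cos(th_k),
                          placed[i, 2] + ring * sin(th_k),
                          b_sigma, b_amplitude)
          }
        }
      }
      truth_rows[[cell]] <- data.frame(
        cell = cell,
        a_focus_id = (aid - nrow(placed) + 1L):aid,
        x_um = placed[, 1] * pixel_size,
        y_um = placed[, 2] * pixel_size,
        n_nested = nested)
    }
  }
  if (noise_gaussian_sd > 0) {
    chA <- chA + matrix(stats::rnorm(H * W, 0, noise_gaussian_sd), H, W)
    chB <- chB + matrix(stats::rnorm(H * W, 0, noise_gaussian_sd), H, W)
    edu <- edu + matrix(stats::rnorm(H * W, 0, noise_gaussian_sd), H, W)
  }
  clamp <- function(m) pmin(pmax(m, 0), 255)
  truth <- do.call(rbind, truth_rows)
  if (is.null(truth))
    truth <- data.frame(cell = integer(0), a_focus_id = integer(0),
                        x_um = numeric(0), y_um = numeric(0),
                        n_nested = integer(0))
  rownames(truth) <- NULL
  list(channel_a = clamp(chA), channel_b = clamp(chB), edu = clamp(edu),
       truth = truth,
       cells = data.frame(cell = seq_len(n_cells), edu_positive = edu_pos),
       nucleus_labels = nuc_lab,
       pixel_size = pixel_size)
}
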