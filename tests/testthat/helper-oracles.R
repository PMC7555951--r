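# Shared fixtures and independent oracles used across the suite.

# Render a sum of isotropic 2-D Gaussians on an H x W canvas.
# centers: matrix of (x, y) in 0-based pixel coordinates.
gaussian_spots_image <- function(H, W, centers, sigma, amplitude = 200,
                                 background = 0) {
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  img <- matrix(background, H, W)
  for (i in seq_len(nrow(centers)))
    img <- img + amplitude *
      exp(-((xs - centers[i, 1])^2 + (ys - centers[i, 2])^2) / (2 * sigma^2))
  img
}

# Brute-force greedy assignment oracle for frame linking: repeatedly scan
# the full distance matrix for the admissible pair of minimal distance
# (ties broken by ascending labels), independent of the vectorized
# implementation in link_frames().
oracle_greedy_links <- function(pt, pt1, maxd, inclusive = FALSE) {
  links <- data.frame(from = integer(0), to = integer(0),
                      distance_um = numeric(0))
  repeat {
    best <- NULL
    for (i in seq_len(nrow(pt))) {
      if (pt$label[i] %in% links$from) next
      for (j in seq_len(nrow(pt1))) {
        if (pt1$label[j] %in% links$to) next
        d <- sqrt((pt$com_x_um[i] - pt1$com_x_um[j])^2 +
                  (pt$com_y_um[i] - pt1$com_y_um[j])^2)
        adm <- if (inclusive) d <= maxd else d < maxd
        if (!adm) next
        if (is.null(best) || d < best$d ||
            (d == best$d && (pt$label[i] < best$from ||
              (pt$label[i] == best$from && pt1$label[j] < best$to)))) {
          best <- list(d = d, from = pt$label[i], to = pt1$label[j])
        }
      }
    }
    if (is.null(best)) break
    links <- rbind(links, data.frame(from = best$from, to = best$to,
                                     distance_um = best$d))
  }
  links <- links[order(links$from), , drop = FALSE]
  rownames(links) <- NULL
  links
}

# Match detected foci to ground-truth identities per frame (nearest truth
# position within tol um), then score frame-to-frame link recovery of the
# built tracks against the truth lineage.
link_fidelity <- function(sim, result, tol = 0.3) {
  n_fr <- sim$config$n_frames
  det <- result$foci
  mm <- do.call(rbind, lapply(0:(n_fr - 1), function(t) {
    dt <- det[det$frame == t, ]
    tt <- sim$truth[sim$truth$frame == t, ]
    if (!nrow(dt) || !nrow(tt)) return(NULL)
    d <- sqrt(outer(dt$com_x_um, tt$x_um, "-")^2 +
              outer(dt$com_y_um, tt$y_um, "-")^2)
    m <- apply(d, 1, which.min)
    ok <- d[cbind(seq_len(nrow(dt)), m)] < tol
    data.frame(frame = t, label = dt$label,
               truth = ifelse(ok, tt$focus_id[m], NA))
  }))
  n_true_links <- sum(sapply(0:(n_fr - 2), function(t)
    length(intersect(sim$truth$focus_id[sim$truth$frame == t],
                     sim$truth$focus_id[sim$truth$frame == t + 1]))))
  tk <- merge(result$tracks, mm, by = c("frame", "label"))
  rec <- 0; spur <- 0; totl <- 0
  for (t in 0:(n_fr - 2)) {
    j <- merge(tk[tk$frame == t, ], tk[tk$frame == t + 1, ],
               by = "track_id")
    totl <- totl + nrow(j)
    good <- !is.na(j$truth.x) & !is.na(j$truth.y) & j$truth.x == j$truth.y
    rec <- rec + sum(good)
    spur <- spur + sum(!good)
  }
  list(recall = rec / n_true_links,
       spurious = spur / max(totl, 1),
       n_true_links = n_true_links, n_detected_links = totl)
}

# Low-density confined time-lapse used for linker fidelity checks: initial
# spacing (1.8 um) is more than 3x the expected rms diffusion step
# (sqrt(4 * 0.001 * 20) = 0.28 um) and confinement keeps foci apart for
# the whole run.
low_density_sim <- function(seed = 1L) {
  simulate_timelapse(sim_config(
    n_frames = 25, n_initial_foci = 6,
    diffusion_coefficient = 0.001, confinement_radius = 0.5,
    min_initial_spacing = 1.8, noise_gaussian_sd = 1, seed = seed))
}
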