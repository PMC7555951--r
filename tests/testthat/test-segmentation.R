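test_that("max projection takes the per-pixel maximum over z", {
  m1 <- matrix(3, 4, 4); m2 <- matrix(7, 4, 4)
  st <- array(c(m1, m2), c(4, 4, 2))
  expect_equal(max_project(st), m2)
  expect_equal(max_project(array(m1, c(4, 4, 1))), m1)
  expect_equal(max_project(array(0, c(4, 4, 2))), matrix(0, 4, 4))
  expect_error(max_project(array(0, c(4, 4, 0))), "planes")
})

test_that("nucleus segmentation finds discs and applies the border rule", {
  img <- gaussian_spots_image(100, 100, matrix(numeric(0), 0, 2), 1)
  xs <- matrix(rep(0:99, each = 100), 100, 100)
  ys <- matrix(rep(0:99, 100), 100, 100)
  img[(xs - 25)^2 + (ys - 30)^2 < 15^2] <- 150
  img[(xs - 70)^2 + (ys - 65)^2 < 15^2] <- 150
  expect_equal(max(segment_nuclei(img)), 2)

  # blank image: zero nuclei
  expect_equal(max(segment_nuclei(matrix(5, 50, 50))), 0)

  # a disc across the border is excluded
  img2 <- matrix(0, 100, 100)
  img2[(xs - 0)^2 + (ys - 50)^2 < 15^2] <- 150
  expect_equal(max(segment_nuclei(img2)), 0)
  expect_equal(max(segment_nuclei(img2, exclude_border = FALSE)), 1)
})

test_that("frame statistics use the sample (n-1) standard deviation", {
  img <- matrix(10, 5, 5)
  mask <- matrix(TRUE, 5, 5)
  s <- compute_frame_stats(img, mask, 0)
  expect_equal(s$mean_intensity, 10)
  expect_equal(s$sd_intensity, 0)

  img2 <- matrix(c(0, 2, 4, 0, 0, 0), 2, 3)
  mask2 <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), 2, 3)
  s2 <- compute_frame_stats(img2, mask2, 1)
  expect_equal(s2$mean_intensity, 2)
  expect_equal(s2$sd_intensity, 2)   # sd({0,2,4}) with n-1

  expect_error(compute_frame_stats(img, matrix(FALSE, 5, 5), 3), "frame 3")
})

test_that("threshold factor calibration and per-frame threshold are exact inverses", {
  s0 <- data.frame(frame = 0L, mean_intensity = 40, sd_intensity = 20)
  m <- calibrate_threshold_factor(100, s0)
  expect_equal(m$factor, 3)
  expect_equal(calibrate_threshold_factor(40, s0)$factor, 0)
  expect_error(calibrate_threshold_factor(
    100, data.frame(frame = 0L, mean_intensity = 10, sd_intensity = 0)),
    "frame 0")

  st <- data.frame(frame = 1L, mean_intensity = 50, sd_intensity = 10)
  expect_equal(frame_threshold(st, m), 80)
  m0 <- calibrate_threshold_factor(40, s0)  # factor 0
  expect_equal(frame_threshold(st, m0), st$mean_intensity)
  # algebraic identity on the calibration frame itself
  expect_equal(frame_threshold(s0, m), 100)
})

test_that("focus segmentation separates touching spots and measures them", {
  # one clear spot
  img1 <- gaussian_spots_image(32, 32, cbind(15, 15), sigma = 2)
  expect_equal(max(segment_foci(img1, 40)), 1)

  # two spots (sigma 2) 5 px apart, merged at threshold -> watershed gives 2
  img2 <- gaussian_spots_image(32, 32, rbind(c(13.5, 15.5), c(18.5, 15.5)),
                               sigma = 2)
  bin <- img2 >= 40
  expect_equal(max(EBImage::bwlabel(bin)), 1)  # genuinely merged
  expect_equal(max(segment_foci(img2, 40)), 2)

  # nothing above threshold
  expect_equal(max(segment_foci(img1, 500)), 0)
})

test_that("focus measurements follow the weighted-centroid arithmetic", {
  img <- matrix(0, 6, 6); img[2:3, 2:3] <- 10
  lab <- matrix(0L, 6, 6); lab[2:3, 2:3] <- 1L
  f <- measure_foci(lab, img, pixel_size = 0.5)
  expect_equal(f$area_um2, 1.0)
  expect_equal(f$mean_intensity, 10)
  expect_equal(f$total_intensity, 10)
  expect_equal(f$com_x_um, 1.5 * 0.5)   # pixels 1,2 (0-based) -> center 1.5
  expect_equal(f$com_y_um, 1.5 * 0.5)

  # intensity-weighted COM: intensities 1 and 3 at x = 0, 1
  img2 <- matrix(0, 3, 3); img2[2, 1] <- 1; img2[2, 2] <- 3
  lab2 <- matrix(0L, 3, 3); lab2[2, 1] <- 1L; lab2[2, 2] <- 1L
  f2 <- measure_foci(lab2, img2, pixel_size = 1, com_type = "intensity")
  expect_equal(f2$com_x_um, 0.75)
  f2g <- measure_foci(lab2, img2, pixel_size = 1, com_type = "geometric")
  expect_equal(f2g$com_x_um, 0.5)

  expect_equal(nrow(measure_foci(matrix(0L, 3, 3), img2, 1)), 0)
})

test_that("label maps are a partition with positive-area labels", {
  sim <- simulate_timelapse(sim_config(n_frames = 1, n_initial_foci = 7,
                                       seed = 21, noise_gaussian_sd = 0))
  img <- sim$stack[, , 1]
  lab <- segment_foci(img, 80, min_area = 0)
  expect_true(all(lab >= 0))
  counts <- tabulate(lab[lab > 0], nbins = max(lab))
  expect_true(all(counts > 0))
})

test_that("detected COMs match ground truth within a pixel on noise-free frames", {
  cfg <- sim_config(n_frames = 1, n_initial_foci = 6, seed = 13,
                    noise_gaussian_sd = 0, min_initial_spacing = 1.2)
  sim <- simulate_timelapse(cfg)
  img <- sim$stack[, , 1]
  lab <- segment_foci(img, 80)
  f <- measure_foci(lab, img, cfg$pixel_size)
  tt <- sim$truth
  expect_equal(nrow(f), nrow(tt))
  d <- sqrt(outer(f$com_x_um, tt$x_um, "-")^2 +
            outer(f$com_y_um, tt$y_um, "-")^2)
  expect_lt(max(apply(d, 1, min)), cfg$pixel_size)  # within 1 px
})

test_that("rigid registration recovers known translations and rotations", {
  cfg <- sim_config(n_frames = 1, n_initial_foci = 6, seed = 5,
                    noise_gaussian_sd = 0)
  f0 <- simulate_timelapse(cfg)$stack[, , 1]

  # identical frames: identity alignment
  st0 <- array(c(f0, f0), c(dim(f0), 2))
  r0 <- register_stack(st0, max_rotation = 0)
  expect_equal(r0$stack, st0)

  # pure translation: exact recovery
  f1 <- transform_rigid(f0, 0, c(3, -2))
  st1 <- array(c(f0, f1), c(dim(f0), 2))
  r1 <- register_stack(st1, max_rotation = 0)
  expect_equal(c(r1$transforms$dx_px[2], r1$transforms$dy_px[2]), c(-3, 2))
  expect_lt(mean(abs(r1$stack[, , 2] - f0)), 1e-8)

  # 5 degree rotation about the image center: recovered within 0.5 degrees
  f2 <- transform_rigid(f0, 5, c(0, 0))
  st2 <- array(c(f0, f2), c(dim(f0), 2))
  r2 <- register_stack(st2, max_rotation = 10)
  expect_lt(abs(abs(r2$transforms$angle_deg[2]) - 5), 0.5)

  # degenerate constant frames pass through with a warning
  flat <- array(1, c(16, 16, 2))
  expect_warning(rf <- register_stack(flat), "constant")
  expect_equal(rf$stack, flat)
})

test_that("affine intensity rescaling leaves factor and focus masks unchanged", {
  cfg <- sim_config(n_frames = 3, n_initial_foci = 5, seed = 17)
  sim <- simulate_timelapse(cfg)
  nmask <- sim$nucleus_mask
  alpha <- 1.8; beta <- 12
  L <- 95
  for (t in 1:3) {
    img <- sim$stack[, , t]
    img_t <- alpha * img + beta
    s <- compute_frame_stats(img, nmask, t - 1L)
    s_t <- compute_frame_stats(img_t, nmask, t - 1L)
    m <- calibrate_threshold_factor(L, s)
    m_t <- calibrate_threshold_factor(alpha * L + beta, s_t)
    expect_equal(m_t$factor, m$factor, tolerance = 1e-10)
    lab <- segment_foci(img, frame_threshold(s, m),
                        upper_threshold = Inf, mask = nmask)
    lab_t <- segment_foci(img_t, frame_threshold(s_t, m_t),
                          upper_threshold = Inf, mask = nmask)
    expect_identical(lab > 0, lab_t > 0)
  }
})
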