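test_that("single-track MSD matches hand-computed and closed-form cases", {
  # stationary
  st <- compute_track_msd(cbind(rep(1, 5), rep(2, 5)), 20)
  expect_true(all(st$msd_um2 == 0))

  # hand example: positions 0, 1, 2 um on a line
  cv <- compute_track_msd(cbind(c(0, 1, 2), c(0, 0, 0)), 20)
  expect_equal(cv$msd_um2, c(1, 4))
  expect_equal(cv$lag_min, c(20, 40))
  expect_equal(cv$n_pairs, c(2, 1))

  # ballistic: step s per frame -> MSD(n dt) = (n s)^2
  s <- 0.3
  pos <- cbind(s * (0:9), rep(0, 10))
  bal <- compute_track_msd(pos, 20)
  expect_equal(bal$msd_um2, (s * (1:9))^2, tolerance = 1e-12)

  # single-focus track: empty curve
  expect_equal(nrow(compute_track_msd(cbind(1, 1), 20)), 0)
})

test_that("ensemble MSD averages per-track curves and truncates support", {
  tr1 <- cbind(c(0, 1, 2), c(0, 0, 0))
  one <- ensemble_msd(list(tr1), 20, min_tracks = 1)
  expect_equal(one$msd_um2, compute_track_msd(tr1, 20)$msd_um2)

  zero <- ensemble_msd(list(cbind(rep(0, 4), rep(0, 4)),
                            cbind(rep(1, 4), rep(1, 4))), 20, min_tracks = 2)
  expect_true(all(zero$msd_um2 == 0))

  expect_warning(e <- ensemble_msd(list(), 20), "no tracks")
  expect_equal(nrow(e), 0)
})

test_that("through-origin diffusion fit recovers exact and simulated D", {
  # exact line y = 0.04 t -> a = 0.04, D = 0.01
  cv <- data.frame(lag_min = (1:6) * 20, msd_um2 = 0.04 * (1:6) * 20)
  fit <- fit_diffusion_coefficient(cv)
  expect_equal(fit$slope, 0.04)
  expect_equal(fit$D, 0.01)
  expect_equal(fit$n_points, 4)

  # all-zero MSD
  z <- data.frame(lag_min = (1:4) * 20, msd_um2 = rep(0, 4))
  expect_equal(fit_diffusion_coefficient(z)$D, 0)

  expect_error(fit_diffusion_coefficient(
    data.frame(lag_min = 20, msd_um2 = 1)), "at least 2")

  # parameter recovery on simulated free ensembles
  set.seed(77)
  D <- 0.005
  tracks <- lapply(1:500, function(i)
    simulate_brownian_track(D, n_steps = 10, dt = 20))
  em <- ensemble_msd(tracks, 20)
  rec <- fit_diffusion_coefficient(em)
  expect_lt(abs(rec$D - D) / D, 0.1)
})

test_that("apparent D decreases with tighter confinement at fixed true D", {
  Ds <- sapply(c(Inf, 1.0, 0.4), function(r) {
    set.seed(55)
    tracks <- lapply(1:300, function(i)
      simulate_brownian_track(0.01, n_steps = 12, dt = 20,
                              confinement_radius = r))
    fit_diffusion_coefficient(ensemble_msd(tracks, 20))$D
  })
  expect_true(all(diff(Ds) < 0))
})

test_that("focus time series averages per frame and keeps empty frames missing", {
  f <- data.frame(frame = c(0, 0, 2), mean_intensity = c(10, 10, 12),
                  area_um2 = c(2, 2, 2), total_intensity = c(20, 20, 24))
  ts <- focus_timeseries(f, n_frames = 3)
  expect_equal(ts$mean_total[1], 20)
  expect_true(is.na(ts$mean_total[2]))   # empty frame: missing, not zero
  expect_equal(ts$n_foci, c(2L, 0L, 1L))

  # intensity growth in a noise-free simulation is monotone in the measurements
  cfg <- sim_config(n_frames = 8, n_initial_foci = 5, amplitude_growth = 0.05,
                    noise_gaussian_sd = 0, seed = 19,
                    min_initial_spacing = 1.2)
  sim <- simulate_timelapse(cfg)
  res <- run_pipeline(run_config(output_dir = withr::local_tempdir(),
                                 threshold_factor = 3),
                      stack = sim$stack)
  ts2 <- focus_timeseries(res$foci, 8)
  expect_true(all(diff(ts2$mean_intensity) > 0))
})

test_that("anchored KDE preserves histogram area and equal-area scaling", {
  set.seed(3)
  v <- rnorm(300, 100, 15)
  k <- kde_distribution(v, bandwidth = 6)
  expect_lt(abs(density_curve_area(k) - k$histogram_area) /
              k$histogram_area, 0.01)

  # single repeated value (with a hair of jitter to allow 2 distinct):
  # symmetric unimodal curve peaking at v
  vv <- c(rep(50, 100), 50 + 1e-9)
  k2 <- kde_distribution(vv, bandwidth = 2)
  expect_lt(abs(k2$x[which.max(k2$y)] - 50), 0.1)

  # two conditions scaled to equal area -> equal curve integrals
  a <- rnorm(400, 90, 10); b <- rnorm(250, 110, 20)
  ka <- kde_distribution(a, bandwidth = 6)
  kb <- kde_distribution(b, bandwidth = 6,
                         target_area = ka$histogram_area)
  expect_lt(abs(density_curve_area(ka) - density_curve_area(kb)) /
              density_curve_area(ka), 0.01)

  # t=0 anchor: the same normalization factor is reused later
  k0 <- kde_distribution(a, bandwidth = 6)
  k1 <- kde_distribution(a + 5, bandwidth = 6,
                         normalization_factor = k0$normalization_factor)
  expect_equal(k1$normalization_factor, k0$normalization_factor)

  expect_error(kde_distribution(a, bandwidth = -1), "positive")
  expect_error(kde_distribution(1, bandwidth = 1), "at least 2")
})

test_that("MSD shape classification separates free from confined motion", {
  # exact line -> linear
  lin <- data.frame(lag_min = (1:8) * 20, msd_um2 = 0.02 * (1:8) * 20)
  expect_equal(classify_msd_shape(lin)$shape, "linear")

  # exact plateau with small tau -> saturating
  t <- (1:8) * 20
  sat <- data.frame(lag_min = t, msd_um2 = 0.5 * (1 - exp(-t / 15)))
  expect_equal(classify_msd_shape(sat)$shape, "saturating")

  # too-short curve -> indeterminate
  expect_equal(classify_msd_shape(lin[1:4, ])$shape, "indeterminate")

  # simulated ensembles at fixed seed
  set.seed(91)
  free <- lapply(1:300, function(i) simulate_brownian_track(0.01, 12, 20))
  expect_equal(classify_msd_shape(ensemble_msd(free, 20))$shape, "linear")
  set.seed(91)
  conf <- lapply(1:300, function(i)
    simulate_brownian_track(0.05, 30, 20, confinement_radius = 0.5))
  expect_equal(classify_msd_shape(ensemble_msd(conf, 20))$shape, "saturating")
})
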