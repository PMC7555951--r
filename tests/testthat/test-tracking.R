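foci_row <- function(label, x, y) {
  data.frame(label = as.integer(label), com_x_um = x, com_y_um = y)
}

test_that("frame linking applies the strict distance criterion", {
  a <- foci_row(1, 0, 0)
  expect_equal(nrow(link_frames(a, foci_row(1, 0.5, 0))$links), 1)
  # exactly at the cutoff: excluded under the strict reading
  expect_equal(nrow(link_frames(a, foci_row(1, 0.7, 0))$links), 0)
  expect_equal(nrow(link_frames(a, foci_row(1, 0.7, 0),
                                inclusive = TRUE)$links), 1)
  # empty inputs
  e <- link_frames(a[0, ], foci_row(1, 0, 0))
  expect_equal(nrow(e$links), 0)
})

test_that("splits and merges are recorded while one continuing link is kept", {
  # one focus equidistant from two candidates: tie broken by lowest label
  a <- foci_row(1, 0, 0)
  b <- rbind(foci_row(1, 0.3, 0), foci_row(2, -0.3, 0))
  ls <- link_frames(a, b)
  expect_equal(nrow(ls$links), 1)
  expect_equal(ls$links$to, 1)
  expect_equal(ls$splits$from, 1)
  expect_equal(ls$splits$to_candidates, "1,2")

  # two foci sharing one candidate: merge event, nearest wins
  a2 <- rbind(foci_row(1, 0, 0), foci_row(2, 0.4, 0))
  b2 <- foci_row(1, 0.25, 0)
  ls2 <- link_frames(a2, b2)
  expect_equal(nrow(ls2$links), 1)
  expect_equal(ls2$links$from, 2)   # distance 0.15 < 0.25
  expect_equal(ls2$merges$to, 1)
  expect_equal(ls2$merges$from_candidates, "1,2")
})

test_that("linker equals the brute-force greedy oracle on small instances", {
  set.seed(31)
  for (rep in 1:60) {
    n_a <- sample(0:6, 1); n_b <- sample(0:6, 1)
    a <- foci_row(seq_len(n_a), runif(n_a, 0, 2.5), runif(n_a, 0, 2.5))
    b <- foci_row(seq_len(n_b), runif(n_b, 0, 2.5), runif(n_b, 0, 2.5))
    got <- link_frames(a, b, 0.7)$links
    want <- oracle_greedy_links(a, b, 0.7)
    expect_equal(got$from, want$from)
    expect_equal(got$to, want$to)
    expect_equal(got$distance_um, want$distance_um, tolerance = 1e-12)
  }
})

test_that("track building produces gap-free tracks covering every focus", {
  # one focus present in all 51 frames -> a single track, duration 1000 min
  frames <- lapply(0:50, function(t) {
    f <- foci_row(1, 0.01 * t, 0)
    f$frame <- t; f$area_um2 <- 0.2; f$mean_intensity <- 100
    f$total_intensity <- 20
    f
  })
  tr <- build_tracks(frames, frame_interval = 20)
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 51)
  expect_equal(unique(tr$duration_min), 1000)

  # a focus present in a single frame: duration 0
  one <- lapply(0:2, function(t) {
    if (t != 1) return(foci_row(integer(0), numeric(0), numeric(0)))
    f <- foci_row(1, 5, 5); f$frame <- t
    f$area_um2 <- 0.1; f$mean_intensity <- 50; f$total_intensity <- 5
    f
  })
  tr1 <- build_tracks(one, frame_interval = 20)
  expect_equal(nrow(tr1), 1)
  expect_equal(tr1$duration_min, 0)
})

test_that("track membership partitions the foci and steps stay below the cutoff", {
  sim <- low_density_sim(seed = 3)
  res <- run_pipeline(run_config(output_dir = withr::local_tempdir(),
                                 threshold_factor = 3),
                      stack = sim$stack)
  tr <- res$tracks
  # every segmented focus appears exactly once
  expect_equal(nrow(tr), nrow(res$foci))
  expect_false(any(duplicated(tr[, c("frame", "label")])))
  # all within-track consecutive displacements below the linking distance
  by_track <- split(tr, tr$track_id)   # rows already ordered by frame
  for (g in by_track) {
    if (nrow(g) < 2) next
    expect_equal(diff(g$frame), rep(1, nrow(g) - 1))   # gap-free
    d <- sqrt(diff(g$com_x_um)^2 + diff(g$com_y_um)^2)
    expect_true(all(d < 0.7))
  }
  # durations are nonnegative multiples of the frame interval
  expect_true(all(tr$duration_min %% 20 == 0))
  expect_true(all(tr$duration_min >= 0))
})

test_that("track duration follows (n - 1) * interval", {
  expect_equal(track_duration(51, 20), 1000)
  expect_equal(track_duration(2, 20), 20)
  expect_equal(track_duration(1, 20), 0)
  expect_error(track_duration(data.frame()), "at least one")
})

test_that("duration binning maps closed intervals plus overflow", {
  tt <- data.frame(track_id = 1:6,
                   duration_min = c(60, 100, 420, 20, 400, 0))
  b <- bin_tracks_by_duration(tt)
  expect_equal(as.character(b$group),
               c("20-80", "100-160", "overflow", "20-80", "340-400",
                 "single-frame"))
  expect_false(anyNA(b$group))
})

test_that("per-frame counts follow the ground truth at low density", {
  sim <- low_density_sim(seed = 2)
  res <- run_pipeline(run_config(output_dir = withr::local_tempdir(),
                                 threshold_factor = 3),
                      stack = sim$stack)
  cnt <- foci_per_frame(split(res$foci, res$foci$frame),
                        n_frames = sim$config$n_frames)
  truth_cnt <- as.integer(table(factor(sim$truth$frame,
                                       levels = 0:(sim$config$n_frames - 1))))
  expect_true(mean(cnt$summary$mean_foci == truth_cnt) >= 0.9)

  blank <- foci_per_frame(data.frame(frame = integer(0)), n_frames = 5)
  expect_true(all(is.na(blank$summary$mean_foci) |
                  blank$summary$mean_foci == 0))
})

test_that("count correlation reports exact linear relations", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(correlate_counts(x, x)$r_squared, 1)
  expect_equal(correlate_counts(x, 2 * x)$r_squared, 1)
  r <- correlate_counts(c(1, 2, 3), c(3, 2, 1))
  expect_equal(r$r_squared, 1)
  expect_equal(r$slope, -1)
  expect_warning(rz <- correlate_counts(c(2, 2, 2), c(1, 2, 3)), "zero-variance")
  expect_true(is.na(rz$r_squared))
})
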