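#' Pipeline run configuration
#'
#' Validated configuration for [run_pipeline()]. Holds the acquisition
#' geometry (pixel size, frame interval), the segmentation and linking
#' constants (manual threshold or precalibrated factor, 0.7 um linking
#' distance, duration bins) and the KDE bandwidths. Round-trips
#' losslessly through YAML via [write_run_config()] / [read_run_config()].
#'
#' @param input path to a multi-page TIFF time-lapse (ignored when the
#'   pipeline is handed an in-memory stack).
#' @param output_dir directory for result tables and the manifest.
#' @param pixel_size micrometres per pixel (> 0).
#' @param frame_interval minutes between frames (> 0).
#' @param max_link_distance linking distance, micrometres.
#' @param manual_threshold manually chosen lower threshold on the first
#'   frame (8-bit units); mutually exclusive with `threshold_factor`.
#' @param threshold_factor precalibrated dimensionless threshold factor.
#' @param min_focus_area minimum focus area, pixels.
#' @param register stabilize the stack by rigid-body registration first.
#' @param duration_bins list of `c(lo, hi)` duration bins, minutes.
#' @param kde_bandwidths named numeric: bandwidths for `intensity`,
#'   `area`, `total`.
#' @param seed integer seed recorded in the manifest.
#' @return object of class `run_config`.
#' @export
run_config <- function(input = NULL, output_dir = "fociTrack-out",
                       pixel_size = 0.1, frame_interval = 20,
                       max_link_distance = 0.7,
                       manual_threshold = NULL, threshold_factor = NULL,
                       min_focus_area = 4, register = FALSE,
                       duration_bins = list(c(20, 80), c(100, 160),
                                            c(180, 240), c(260, 320),
                                            c(340, 400)),
                       kde_bandwidths = c(intensity = 6, area = 0.3,
                                          total = 220),
                       seed = 1L) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (max_link_distance <= 0) stop("max_link_distance must be > 0")
  if (is.null(manual_threshold) && is.null(threshold_factor))
    stop("provide manual_threshold or threshold_factor")
  structure(list(input = input, output_dir = output_dir,
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 max_link_distance = max_link_distance,
                 manual_threshold = manual_threshold,
                 threshold_factor = threshold_factor,
                 min_focus_area = min_focus_area, register = register,
                 duration_bins = duration_bins,
                 kde_bandwidths = kde_bandwidths,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- unclass(config)
  x$kde_bandwidths <- as.list(x$kde_bandwidths)   # keep names in YAML
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$kde_bandwidths <- unlist(x$kde_bandwidths)
  do.call(run_config, x)
}

#' Run the live-cell focus analysis pipeline on a time-lapse stack
#'
#' Executes the full analysis chain on one cell's time-lapse:
#' (optional rigid-body stabilization) -> nucleus segmentation on the
#' first frame -> adaptive-threshold calibration from the manual
#' threshold on the Gaussian-smoothed first frame -> per-frame focus
#' segmentation with watershed separation -> center-of-mass linking into
#' gap-free tracks -> duration binning, per-frame counts, MSD /
#' diffusion fits and intensity/area/total time series. All tables are
#' written as CSV to `config$output_dir` together with a JSON manifest
#' echoing the configuration and seed; rerunning with identical config
#' and input reproduces identical bytes.
#'
#' @param config a [run_config()].
#' @param stack optional in-memory array `H x W x T` (0--255 scale);
#'   when `NULL`, `config$input` is read with [read_stack_tiff()].
#' @return (invisibly) a list with `foci` (per-frame focus table),
#'   `tracks`, `duration_groups`, `counts`, `timeseries`, `msd`,
#'   `diffusion`, `threshold_model`, `frame_stats`, `manifest_path`.
#' @export
run_pipeline <- function(config, stack = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(stack)) {
    if (is.null(config$input)) stop("no input stack: set config$input")
    stack <- read_stack_tiff(config$input)
  }
  if (!is.array(stack) || length(dim(stack)) != 3L)
    stop("stack must be an H x W x T array")
  n_fr <- dim(stack)[3]
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  # nucleus from the first frame
  nuc <- segment_nuclei(stack[, , 1])
  if (max(nuc) == 0L) {
    # single-cell stacks may fill the field; fall back to the full frame
    nuc <- segment_nuclei(stack[, , 1], exclude_border = FALSE)
  }
  if (max(nuc) == 0L) stop("segmentation: no nucleus found in frame 0")
  # analyze the largest nucleus
  main_nuc <- which.max(tabulate(nuc[nuc > 0]))
  nmask <- nuc == main_nuc

  reg <- NULL
  if (isTRUE(config$register) && n_fr >= 2) {
    reg <- register_stack(stack, nucleus_mask = nmask)
    stack <- reg$stack
  }

  # threshold model: calibrate on the smoothed first frame
  stats_list <- lapply(seq_len(n_fr), function(t)
    compute_frame_stats(stack[, , t], nmask, t - 1L))
  frame_stats <- do.call(rbind, stats_list)
  if (!is.null(config$manual_threshold)) {
    sm0 <- as.matrix(EBImage::gblur(stack[, , 1], 1))
    stats0_sm <- compute_frame_stats(sm0, nmask, 0L)
    model <- calibrate_threshold_factor(config$manual_threshold, stats0_sm)
  } else {
    model <- structure(list(factor = config$threshold_factor,
                            manual_lower_threshold = NA_real_,
                            upper_threshold = 255),
                       class = "threshold_model")
  }

  foci_by_frame <- vector("list", n_fr)
  for (t in seq_len(n_fr)) {
    thr <- frame_threshold(stats_list[[t]], model)
    lab <- segment_foci(stack[, , t], thr,
                        upper_threshold = model$upper_threshold,
                        mask = nmask, min_area = config$min_focus_area)
    foci_by_frame[[t]] <- measure_foci(lab, stack[, , t],
                                       config$pixel_size,
                                       frame_index = t - 1L)
  }
  foci <- do.call(rbind, foci_by_frame)

  tracks <- build_tracks(foci_by_frame,
                         frame_interval = config$frame_interval,
                         max_link_distance = config$max_link_distance)
  groups <- bin_tracks_by_duration(tracks, config$duration_bins)
  counts <- foci_per_frame(foci_by_frame, n_fr)
  ts <- focus_timeseries(foci, n_fr)
  msd <- ensemble_msd(tracks, frame_interval = config$frame_interval)
  diff_fit <- if (nrow(msd[msd$lag_min > 0, ]) >= 2)
    fit_diffusion_coefficient(msd) else NULL

  write_table_csv(foci, file.path(config$output_dir, "foci.csv"))
  write_table_csv(tracks, file.path(config$output_dir, "tracks.csv"))
  write_table_csv(groups, file.path(config$output_dir,
                                    "duration_groups.csv"))
  write_table_csv(counts$summary, file.path(config$output_dir,
                                            "foci_per_frame.csv"))
  write_table_csv(ts, file.path(config$output_dir, "timeseries.csv"))
  write_table_csv(as.data.frame(msd), file.path(config$output_dir,
                                                "msd.csv"))
  manifest <- list(
    package = "fociTrack",
    version = as.character(utils::packageVersion("fociTrack")),
    seed = config$seed,
    config = unclass(config),
    threshold_factor = model$factor,
    n_frames = n_fr, n_foci = nrow(foci),
    n_tracks = length(unique(tracks$track_id)),
    n_nuclei = max(nuc))
  manifest_path <- file.path(config$output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(foci = foci, tracks = tracks, duration_groups = groups,
                 counts = counts, timeseries = ts, msd = msd,
                 diffusion = diff_fit, threshold_model = model,
                 frame_stats = frame_stats, registration = reg,
                 manifest_path = manifest_path))
}

#' Run the fixed-cell two-channel colocalization analysis
#'
#' Segments nuclei (from the A channel), selects EdU-positive nuclei,
#' segments A- and B-channel foci per nucleus, measures B intensity
#' within A masks and reduces nested-focus counts to the 0 / 1 / >1
#' categories. Writes per-focus and category tables as CSV when
#' `output_dir` is given.
#'
#' @param channel_a,channel_b numeric matrices (z-projections) of the two
#'   focus channels (e.g. 53BP1-like and RPA-like markers).
#' @param edu numeric matrix of the S-phase marker channel, or `NULL` to
#'   skip S-phase selection.
#' @param pixel_size micrometres per pixel.
#' @param nucleus_labels optional precomputed nucleus label matrix;
#'   segmented from `channel_a` when `NULL`.
#' @param min_focus_area minimum focus area, pixels.
#' @param output_dir optional output directory for CSV tables.
#' @return list: `nuclei` (per nucleus EdU status), `a_foci`, `b_foci`
#'   (measured focus tables with a `nucleus` column), `b_in_a`
#'   (mean B intensity per A focus), `nested` (per-A-focus counts and
#'   0/1/>1 category fractions).
#' @export
run_colocalization <- function(channel_a, channel_b, edu = NULL,
                               pixel_size = 0.1, nucleus_labels = NULL,
                               min_focus_area = 4, output_dir = NULL) {
  stopifnot(all(dim(channel_a) == dim(channel_b)))
  if (is.null(nucleus_labels))
    nucleus_labels <- segment_nuclei(channel_a, exclude_border = FALSE)
  if (max(nucleus_labels) == 0L) stop("no nuclei found in channel A")
  if (!is.null(edu)) {
    edu_tab <- select_edu_positive(edu, nucleus_labels)
    keep <- edu_tab$nucleus[edu_tab$edu_positive]
  } else {
    edu_tab <- NULL
    keep <- setdiff(sort(unique(as.vector(nucleus_labels))), 0L)
  }
  segA <- segment_fixed_foci(channel_a, nucleus_labels,
                             min_area = min_focus_area, nuclei = keep)
  segB <- segment_fixed_foci(channel_b, nucleus_labels,
                             min_area = min_focus_area, nuclei = keep)
  a_foci <- measure_foci(segA$labels, channel_a, pixel_size)
  if (nrow(a_foci)) a_foci$nucleus <- segA$nucleus_of[a_foci$label]
  b_foci <- measure_foci(segB$labels, channel_b, pixel_size)
  if (nrow(b_foci)) b_foci$nucleus <- segB$nucleus_of[b_foci$label]
  b_in_a <- intensity_in_mask(segA$labels, channel_b)
  nested <- count_b_foci_per_a_focus(segA$labels, b_foci, pixel_size)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_csv(a_foci, file.path(output_dir, "a_foci.csv"))
    write_table_csv(b_foci, file.path(output_dir, "b_foci.csv"))
    write_table_csv(b_in_a, file.path(output_dir, "b_intensity_in_a.csv"))
    write_table_csv(nested$categories,
                    file.path(output_dir, "nested_categories.csv"))
    if (!is.null(edu_tab))
      write_table_csv(edu_tab, file.path(output_dir, "edu_selection.csv"))
  }
  list(nuclei = edu_tab, a_foci = a_foci, b_foci = b_foci,
       b_in_a = b_in_a, nested = nested,
       a_labels = segA$labels, b_labels = segB$labels)
}
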