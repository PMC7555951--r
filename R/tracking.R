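#' Link foci between two consecutive frames by center-of-mass distance
#'
#' Candidate links are pairs of foci whose center-of-mass Euclidean
#' distance is below `max_link_distance` (strictly, by default). Among
#' candidates, assignment is greedy by ascending distance, so each focus
#' joins at most one track-continuing link; ties are broken by ascending
#' focus label for determinism. A focus at `t` with two or more candidates
#' at `t+1` additionally records a split event; two or more foci at `t`
#' sharing a candidate at `t+1` record a merge event.
#'
#' @param foci_t,foci_t1 focus tables for frames `t` and `t+1`, as from
#'   [measure_foci()] (need `label`, `com_x_um`, `com_y_um`).
#' @param max_link_distance maximum linking distance, micrometres
#'   (default 0.7).
#' @param inclusive if `TRUE`, allow distances equal to
#'   `max_link_distance`; the default is a strict `<`.
#' @return list of class `link_set` with
#'   `links` (data.frame `from`, `to`, `distance_um`),
#'   `splits` (data.frame `from`, `to_candidates` as comma-joined labels),
#'   `merges` (data.frame `to`, `from_candidates`).
#' @export
link_frames <- function(foci_t, foci_t1, max_link_distance = 0.7,
                        inclusive = FALSE) {
  empty <- list(links = data.frame(from = integer(0), to = integer(0),
                                   distance_um = numeric(0)),
                splits = data.frame(from = integer(0),
                                    to_candidates = character(0)),
                merges = data.frame(to = integer(0),
                                    from_candidates = character(0)))
  class(empty) <- "link_set"
  if (is.null(foci_t) || is.null(foci_t1) ||
      nrow(foci_t) == 0 || nrow(foci_t1) == 0) return(empty)

  d <- outer(foci_t$com_x_um, foci_t1$com_x_um, "-")^2 +
       outer(foci_t$com_y_um, foci_t1$com_y_um, "-")^2
  d <- sqrt(d)
  cand <- if (inclusive) d <= max_link_distance else d < max_link_distance
  if (!any(cand)) return(empty)

  ij <- which(cand, arr.ind = TRUE)
  cd <- data.frame(i = ij[, 1], j = ij[, 2],
                   from = foci_t$label[ij[, 1]],
                   to = foci_t1$label[ij[, 2]],
                   distance_um = d[ij])
  # deterministic greedy order: distance, then labels
  cd <- cd[order(cd$distance_um, cd$from, cd$to), , drop = FALSE]
  used_i <- logical(nrow(foci_t)); used_j <- logical(nrow(foci_t1))
  pick <- logical(nrow(cd))
  for (k in seq_len(nrow(cd))) {
    if (!used_i[cd$i[k]] && !used_j[cd$j[k]]) {
      pick[k] <- TRUE
      used_i[cd$i[k]] <- TRUE
      used_j[cd$j[k]] <- TRUE
    }
  }
  links <- cd[pick, c("from", "to", "distance_um"), drop = FALSE]
  links <- links[order(links$from), , drop = FALSE]
  rownames(links) <- NULL

  # events from the full candidate sets
  n_to <- table(cd$from)
  split_from <- as.integer(names(n_to)[n_to >= 2])
  splits <- data.frame(
    from = split_from,
    to_candidates = vapply(split_from, function(f)
      paste(sort(cd$to[cd$from == f]), collapse = ","), character(1)))
  n_from <- table(cd$to)
  merge_to <- as.integer(names(n_from)[n_from >= 2])
  merges <- data.frame(
    to = merge_to,
    from_candidates = vapply(merge_to, function(f)
      paste(sort(cd$from[cd$to == f]), collapse = ","), character(1)))
  structure(list(links = links, splits = splits, merges = merges),
            class = "link_set")
}

#' Build gap-free focus tracks from per-frame link sets
#'
#' Chains the greedy frame-to-frame links into maximal tracks. Tracks may
#' start or end at any frame; gaps are impossible by construction (a focus
#' missing in one frame terminates its track). Every segmented focus
#' belongs to exactly one track. New tracks that begin at a split
#' candidate carry a `split_from` annotation naming the parent track;
#' tracks that end by merging into another carry `merged_into`.
#'
#' @param foci_by_frame list of focus tables (one per frame, 0-based frame
#'   order), as from [measure_foci()].
#' @param link_sets list of `link_set` objects for consecutive frame pairs
#'   (`length(foci_by_frame) - 1` of them); computed with
#'   [link_frames()] if `NULL`.
#' @param frame_interval frame interval, minutes.
#' @param max_link_distance linking distance passed to [link_frames()]
#'   when `link_sets` is `NULL`.
#' @return data.frame, one row per focus per frame: `track_id`, `frame`,
#'   `label`, `com_x_um`, `com_y_um`, `area_um2`, `mean_intensity`,
#'   `total_intensity`, `duration_min`, `split_from`, `merged_into`.
#' @export
build_tracks <- function(foci_by_frame, link_sets = NULL,
                         frame_interval = 20, max_link_distance = 0.7) {
  n_fr <- length(foci_by_frame)
  if (n_fr == 0L) stop("no frames supplied")
  if (is.null(link_sets)) {
    link_sets <- vector("list", max(n_fr - 1L, 0L))
    for (t in seq_len(n_fr - 1L))
      link_sets[[t]] <- link_frames(foci_by_frame[[t]],
                                    foci_by_frame[[t + 1L]],
                                    max_link_distance)
  }
  if (length(link_sets) != n_fr - 1L)
    stop("need one link set per consecutive frame pair")

  # assign a track id to every (frame, label)
  track_of <- vector("list", n_fr)   # per frame: named int vector
  next_track <- 1L
  split_from <- integer(0)   # by track id: parent track or NA
  merged_into <- integer(0)
  for (t in seq_len(n_fr)) {
    ft <- foci_by_frame[[t]]
    labs <- if (is.null(ft)) integer(0) else ft$label
    ids <- integer(length(labs))
    names(ids) <- as.character(labs)
    if (t > 1L && length(labs)) {
      lk <- link_sets[[t - 1L]]$links
      prev <- track_of[[t - 1L]]
      for (k in seq_len(nrow(lk)))
        ids[as.character(lk$to[k])] <- prev[as.character(lk$from[k])]
    }
    for (nm in names(ids)[ids == 0L]) {
      ids[nm] <- next_track
      split_from[next_track] <- NA_integer_
      merged_into[next_track] <- NA_integer_
      next_track <- next_track + 1L
    }
    track_of[[t]] <- ids
  }

  # annotate split/merge parentage on the affected tracks
  for (t in seq_len(n_fr - 1L)) {
    ls <- link_sets[[t]]
    if (nrow(ls$splits)) {
      for (k in seq_len(nrow(ls$splits))) {
        parent <- track_of[[t]][as.character(ls$splits$from[k])]
        tos <- as.integer(strsplit(ls$splits$to_candidates[k], ",")[[1]])
        for (to in tos) {
          child <- track_of[[t + 1L]][as.character(to)]
          if (!is.na(child) && child != parent &&
              is.na(split_from[child]))
            split_from[child] <- parent
        }
      }
    }
    if (nrow(ls$merges)) {
      for (k in seq_len(nrow(ls$merges))) {
        into <- track_of[[t + 1L]][as.character(ls$merges$to[k])]
        froms <- as.integer(strsplit(ls$merges$from_candidates[k], ",")[[1]])
        for (fr in froms) {
          loser <- track_of[[t]][as.character(fr)]
          if (!is.na(loser) && loser != into && is.na(merged_into[loser]))
            merged_into[loser] <- into
        }
      }
    }
  }

  rows <- vector("list", n_fr)
  for (t in seq_len(n_fr)) {
    ft <- foci_by_frame[[t]]
    if (is.null(ft) || nrow(ft) == 0) next
    ft$track_id <- as.integer(track_of[[t]][as.character(ft$label)])
    rows[[t]] <- ft
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(track_id = integer(0), frame = integer(0),
                      label = integer(0), com_x_um = numeric(0),
                      com_y_um = numeric(0), area_um2 = numeric(0),
                      mean_intensity = numeric(0),
                      total_intensity = numeric(0),
                      duration_min = numeric(0),
                      split_from = integer(0), merged_into = integer(0)))
  n_foci <- table(out$track_id)
  out$duration_min <- (as.numeric(n_foci[as.character(out$track_id)]) - 1) *
    frame_interval
  out$split_from <- split_from[out$track_id]
  out$merged_into <- merged_into[out$track_id]
  out <- out[order(out$track_id, out$frame),
             c("track_id", "frame", "label", "com_x_um", "com_y_um",
               "area_um2", "mean_intensity", "total_intensity",
               "duration_min", "split_from", "merged_into")]
  rownames(out) <- NULL
  out
}

#' Track duration from the number of linked foci
#'
#' `duration = (number of foci in the track - 1) * frame_interval`: a
#' focus present in a single frame has duration 0; one present in all 51
#' frames of a 20-minute-interval acquisition has duration 1000 min.
#'
#' @param track data.frame of one track's rows (or any object with
#'   `nrow`), or an integer count of foci.
#' @param frame_interval frame interval, minutes.
#' @return duration in minutes.
#' @export
track_duration <- function(track, frame_interval = 20) {
  n <- if (is.numeric(track) && length(track) == 1L) track else nrow(track)
  if (is.null(n) || n < 1) stop("track must contain at least one focus")
  (n - 1) * frame_interval
}

#' Bin tracks into duration groups
#'
#' Assigns each track to the duration group whose closed interval contains
#' its duration. The default groups are 20--80, 100--160, 180--240,
#' 260--320 and 340--400 minutes; longer durations fall into an overflow
#' group, and single-frame tracks (duration 0) are counted separately.
#'
#' @param track_table output of [build_tracks()] (or any data.frame with
#'   `track_id` and `duration_min`).
#' @param bin_edges numeric matrix-like list of `c(lo, hi)` pairs, minutes.
#' @return data.frame, one row per track: `track_id`, `duration_min`,
#'   `group` (factor with the bin labels, `"overflow"`, or
#'   `"single-frame"`).
#' @export
bin_tracks_by_duration <- function(track_table,
                                   bin_edges = list(c(20, 80), c(100, 160),
                                                    c(180, 240), c(260, 320),
                                                    c(340, 400))) {
  tr <- unique(track_table[, c("track_id", "duration_min")])
  labels <- vapply(bin_edges, function(e) paste0(e[1], "-", e[2]),
                   character(1))
  lvls <- c(labels, "overflow", "single-frame")
  grp <- rep(NA_character_, nrow(tr))
  top <- max(vapply(bin_edges, `[`, numeric(1), 2))
  for (k in seq_along(bin_edges)) {
    e <- bin_edges[[k]]
    grp[tr$duration_min >= e[1] & tr$duration_min <= e[2]] <- labels[k]
  }
  grp[tr$duration_min > top] <- "overflow"
  grp[tr$duration_min == 0] <- "single-frame"
  tr$group <- factor(grp, levels = lvls)
  rownames(tr) <- NULL
  tr
}

#' Foci per nucleus per frame
#'
#' Raw per-frame focus counts (independent of tracking), per nucleus, with
#' the across-nuclei mean and standard error per frame.
#'
#' @param foci_tables either a list of per-frame focus tables for a single
#'   nucleus, or a data.frame with columns `frame` and `nucleus`.
#' @param n_frames total number of frames (frames without foci count 0).
#' @return list with `per_nucleus` (data.frame `frame`, `nucleus`,
#'   `n_foci`) and `summary` (data.frame `frame`, `mean_foci`, `sem`,
#'   `n_nuclei`).
#' @export
foci_per_frame <- function(foci_tables, n_frames) {
  if (is.data.frame(foci_tables)) {
    df <- foci_tables
    if (is.null(df$nucleus)) df$nucleus <- rep(1L, nrow(df))
  } else {
    rows <- lapply(seq_along(foci_tables), function(t) {
      ft <- foci_tables[[t]]
      if (is.null(ft) || nrow(ft) == 0) return(NULL)
      data.frame(frame = ft$frame, nucleus = 1L)
    })
    df <- do.call(rbind, rows)
    if (is.null(df)) df <- data.frame(frame = integer(0), nucleus = integer(0))
  }
  nuclei <- if (nrow(df)) sort(unique(df$nucleus)) else 1L
  grid <- expand.grid(frame = 0:(n_frames - 1), nucleus = nuclei)
  if (nrow(df)) {
    cnt <- stats::aggregate(list(n_foci = df$frame),
                            by = list(frame = df$frame, nucleus = df$nucleus),
                            FUN = length)
    per <- merge(grid, cnt, all.x = TRUE)
  } else {
    per <- grid
    per$n_foci <- NA_integer_
  }
  per$n_foci[is.na(per$n_foci)] <- 0L
  per <- per[order(per$nucleus, per$frame), c("frame", "nucleus", "n_foci")]
  rownames(per) <- NULL
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  summ <- do.call(rbind, lapply(split(per, per$frame), function(g)
    data.frame(frame = g$frame[1], mean_foci = mean(g$n_foci),
               sem = sem(g$n_foci), n_nuclei = nrow(g))))
  summ <- summ[order(summ$frame), ]
  rownames(summ) <- NULL
  list(per_nucleus = per, summary = summ)
}

#' Correlate manual and automated focus counts
#'
#' Ordinary least-squares fit of automated counts on manual counts with the
#' coefficient of determination, the summary used to validate script-based
#' counting against manual counting.
#'
#' @param manual,automated paired numeric count vectors, `n >= 3`.
#' @return list with `r_squared`, `slope`, `intercept`, `n`. Zero-variance
#'   input gives `r_squared = NA` with a warning.
#' @export
correlate_counts <- function(manual, automated) {
  stopifnot(length(manual) == length(automated))
  if (length(manual) < 3) stop("need at least 3 paired counts")
  if (stats::sd(manual) == 0 || stats::sd(automated) == 0) {
    warning("zero-variance counts: R^2 undefined")
    return(list(r_squared = NA_real_, slope = NA_real_,
                intercept = NA_real_, n = length(manual)))
  }
  fit <- stats::lm(automated ~ manual)
  # summary.lm warns on exact fits; R^2 = 1 is a legitimate result here
  list(r_squared = suppressWarnings(summary(fit)$r.squared),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(manual))
}
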