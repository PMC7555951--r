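#' Select S-phase (EdU-positive) nuclei by automatic threshold
#'
#' Computes the mean EdU intensity of each nucleus and retains nuclei
#' above an Otsu-style threshold over the per-nucleus means. With a
#' single nucleus (or when the threshold is undefined because all means
#' are identical) a configured absolute cutoff is used instead.
#'
#' @param edu_image numeric matrix of the S-phase marker channel.
#' @param nucleus_labels integer matrix of nucleus labels (0 = background).
#' @param fallback_cutoff absolute mean-intensity cutoff used when the
#'   automatic threshold is undefined.
#' @return data.frame per nucleus: `nucleus`, `mean_edu`, `edu_positive`.
#' @export
select_edu_positive <- function(edu_image, nucleus_labels,
                                fallback_cutoff = 50) {
  stopifnot(all(dim(edu_image) == dim(nucleus_labels)))
  n_nuc <- max(nucleus_labels)
  if (n_nuc == 0L)
    return(data.frame(nucleus = integer(0), mean_edu = numeric(0),
                      edu_positive = logical(0)))
  nz <- nucleus_labels > 0
  means <- as.numeric(tapply(edu_image[nz], nucleus_labels[nz], mean))
  ids <- as.integer(names(tapply(edu_image[nz], nucleus_labels[nz], mean)))
  if (n_nuc == 1L || stats::sd(means) == 0) {
    if (n_nuc > 1L)
      warning("identical per-nucleus EdU means; using fallback cutoff")
    pos <- means >= fallback_cutoff
  } else {
    thr <- .otsu_1d(means)
    pos <- means > thr
  }
  data.frame(nucleus = ids, mean_edu = means, edu_positive = pos)
}

# Otsu threshold on a small 1-D sample: maximize between-class variance
# over midpoints of the sorted unique values.
.otsu_1d <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2) return(u[1])
  cuts <- (u[-1] + u[-length(u)]) / 2
  bcv <- vapply(cuts, function(ct) {
    lo <- x[x <= ct]; hi <- x[x > ct]
    length(lo) * length(hi) * (mean(hi) - mean(lo))^2
  }, numeric(1))
  cuts[which.max(bcv)]
}

#' Segment foci in a fixed-cell channel, per nucleus
#'
#' Within each nucleus, thresholds the channel at the nucleus' own Otsu
#' threshold, separates touching foci by distance-transform watershed and
#' removes blobs below a minimum area. Labels are unique across nuclei.
#'
#' @param image numeric matrix (a z-projection of the channel).
#' @param nucleus_labels integer matrix of nucleus labels.
#' @param min_area minimum focus area, pixels.
#' @param nuclei optional integer vector restricting which nuclei are
#'   processed (e.g. the EdU-positive subset).
#' @return list with `labels` (integer matrix of focus labels, unique
#'   across nuclei) and `nucleus_of` (integer vector mapping focus label
#'   to nucleus).
#' @export
segment_fixed_foci <- function(image, nucleus_labels, min_area = 4,
                               nuclei = NULL) {
  stopifnot(all(dim(image) == dim(nucleus_labels)))
  if (is.null(nuclei)) nuclei <- setdiff(sort(unique(as.vector(nucleus_labels))), 0L)
  out <- matrix(0L, nrow(image), ncol(image))
  nucleus_of <- integer(0)
  offset <- 0L
  for (nuc in nuclei) {
    idx <- which(nucleus_labels == nuc)
    if (length(idx) < 2) next
    H <- nrow(image)
    rows <- range((idx - 1L) %% H) + 1L
    cols <- range((idx - 1L) %/% H) + 1L
    sub_img <- image[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    sub_sel <- nucleus_labels[rows[1]:rows[2], cols[1]:cols[2],
                              drop = FALSE] == nuc
    v <- sub_img[sub_sel]
    if (diff(range(v)) <= .Machine$double.eps) next
    thr <- EBImage::otsu(EBImage::Image(matrix(v)), range = range(v))
    lab <- segment_foci(sub_img, threshold = thr, upper_threshold = Inf,
                        mask = sub_sel, min_area = min_area)
    k <- max(lab)
    if (k == 0L) next
    nzl <- lab > 0
    block <- out[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    block[nzl] <- lab[nzl] + offset
    out[rows[1]:rows[2], cols[1]:cols[2]] <- block
    nucleus_of <- c(nucleus_of, rep(nuc, k))
    offset <- offset + k
  }
  list(labels = out, nucleus_of = nucleus_of)
}

#' Mean channel-B intensity inside each channel-A focus mask
#'
#' Measures, for every A-focus label, the mean pixel intensity of the B
#' channel within that mask -- the resection signal inside each repair
#' focus when A is a 53BP1-like marker and B an RPA-like marker.
#'
#' @param a_focus_labels integer matrix of A-focus labels.
#' @param b_image numeric matrix of the B channel, congruent.
#' @return data.frame: `a_focus`, `mean_b_intensity`.
#' @export
intensity_in_mask <- function(a_focus_labels, b_image) {
  stopifnot(all(dim(a_focus_labels) == dim(b_image)))
  if (max(a_focus_labels) == 0L)
    return(data.frame(a_focus = integer(0), mean_b_intensity = numeric(0)))
  nz <- a_focus_labels > 0
  m <- tapply(b_image[nz], a_focus_labels[nz], mean)
  data.frame(a_focus = as.integer(names(m)), mean_b_intensity = as.numeric(m))
}

#' Count nested B foci per A focus and reduce to 0 / 1 / >1 categories
#'
#' Assigns each B focus to the A focus whose mask contains its center of
#' mass (B foci whose COM lies in no A mask stay unassigned), counts B
#' foci per A focus, and reports the fractions of A foci with 0, 1 and
#' more than one nested B focus. An area-overlap rule is available as an
#' alternative to COM containment.
#'
#' @param a_focus_labels integer matrix of A-focus labels.
#' @param b_foci data.frame of measured B foci (needs `label`, `com_x_um`,
#'   `com_y_um`) as from [measure_foci()], or `NULL`/empty for none.
#' @param pixel_size micrometres per pixel (to map COMs to pixels).
#' @param b_focus_labels required for `rule = "overlap"`: integer matrix
#'   of B-focus labels.
#' @param rule `"com"` (default): COM containment; `"overlap"`: assign a
#'   B focus to the A focus covering >= 50% of its area.
#' @return list: `per_a_focus` (data.frame `a_focus`, `n_nested`),
#'   `categories` (data.frame `category` in `c("0","1",">1")`, `count`,
#'   `fraction`), `n_unassigned_b`.
#' @export
count_b_foci_per_a_focus <- function(a_focus_labels, b_foci, pixel_size,
                                     b_focus_labels = NULL,
                                     rule = c("com", "overlap")) {
  rule <- match.arg(rule)
  n_a <- max(a_focus_labels)
  a_ids <- seq_len(n_a)
  counts <- integer(n_a)
  unassigned <- 0L
  if (!is.null(b_foci) && nrow(b_foci) > 0) {
    if (rule == "com") {
      col <- round(b_foci$com_x_um / pixel_size) + 1L
      row <- round(b_foci$com_y_um / pixel_size) + 1L
      col <- pmin(pmax(col, 1L), ncol(a_focus_labels))
      row <- pmin(pmax(row, 1L), nrow(a_focus_labels))
      owner <- a_focus_labels[cbind(row, col)]
      unassigned <- sum(owner == 0L)
      tb <- table(owner[owner > 0L])
      counts[as.integer(names(tb))] <- as.integer(tb)
    } else {
      stopifnot(!is.null(b_focus_labels))
      for (b in b_foci$label) {
        sel <- b_focus_labels == b
        ov <- a_focus_labels[sel]
        tb <- table(ov[ov > 0])
        if (length(tb) && max(tb) >= 0.5 * sum(sel)) {
          a <- as.integer(names(tb)[which.max(tb)])
          counts[a] <- counts[a] + 1L
        } else unassigned <- unassigned + 1L
      }
    }
  }
  per <- data.frame(a_focus = a_ids, n_nested = counts)
  cat_of <- ifelse(counts == 0L, "0", ifelse(counts == 1L, "1", ">1"))
  cats <- c("0", "1", ">1")
  cnt <- vapply(cats, function(cc) sum(cat_of == cc), integer(1))
  categories <- data.frame(category = cats, count = cnt,
                           fraction = if (n_a > 0) cnt / n_a else rep(NA_real_, 3))
  list(per_a_focus = per, categories = categories,
       n_unassigned_b = unassigned)
}
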