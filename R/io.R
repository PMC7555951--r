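#' Write an image stack to a multi-page TIFF
#'
#' One page per frame, stored as 8-bit after clamping to 0--255 (the
#' intensity convention of the adaptive threshold model). Intensities are
#' divided by 255 for storage and restored on read.
#'
#' @param stack numeric array `H x W x T` or a matrix (single page), on
#'   the 0--255 scale.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1L))
  pages <- lapply(seq_len(dim(stack)[3]), function(k)
    pmin(pmax(stack[, , k], 0), 255) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a multi-page TIFF into an image stack
#'
#' Returns intensities on the 0--255 scale regardless of stored bit
#' depth (higher-bit-depth inputs are linearly rescaled; the scaling is
#' reported in the run manifest by [run_pipeline()]).
#'
#' @param path TIFF file path.
#' @return numeric array `H x W x T` on the 0--255 scale.
#' @export
read_stack_tiff <- function(path) {
  if (!file.exists(path)) stop("TIFF not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # first channel of RGB pages
    p * 255
  })
  array(unlist(pages), c(dim(pages[[1]]), length(pages)))
}

#' Write a data frame as CSV with units encoded in the header
#'
#' Thin wrapper around [utils::write.csv()] that keeps row names off and
#' uses deterministic formatting so repeated runs are byte-identical.
#'
#' @param df data.frame (column names carry units, e.g. `com_x_um`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
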