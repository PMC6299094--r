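# Core containers: ground truth records and image stacks.

#' Ground truth record for synthetic data
#'
#' Every synthetic generator attaches one of these to its output so that
#' downstream recovery can be asserted against known parameters. Physical
#' magnitudes must be non-negative, the anomalous exponent in (0, 2], and any
#' collagen fraction in \[0, 100\].
#'
#' @param ... named generative parameters (e.g. `diffusion_coeff`, `cbf`,
#'   `mct_rate`, `collagen_fraction`, `seed`)
#' @return an object of class `ground_truth` (a named list)
#' @export
ground_truth <- function(...) {
  gt <- list(...)
  if (is.null(names(gt)) || any(names(gt) == ""))
    stop_invalid("all ground_truth fields must be named")
  if (!is.null(gt$anomalous_exponent) &&
      (gt$anomalous_exponent <= 0 || gt$anomalous_exponent > 2))
    stop_invalid("anomalous_exponent must lie in (0, 2]")
  if (!is.null(gt$collagen_fraction) &&
      (gt$collagen_fraction < 0 || gt$collagen_fraction > 100))
    stop_invalid("collagen_fraction must lie in [0, 100]")
  for (f in c("diffusion_coeff", "localization_sigma", "asl_depth",
              "pcl_depth", "cbf")) {
    if (!is.null(gt[[f]]) && any(gt[[f]] < 0))
      stop_invalid("ground truth field `%s` must be non-negative", f)
  }
  structure(gt, class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    if (is.numeric(v)) v <- paste(fmt_num(v), collapse = ", ")
    cat(sprintf("  %s: %s\n", nm, paste(v, collapse = ", ")))
  }
  invisible(x)
}

#' Multi-frame image stack
#'
#' Container for movie data: bead movies, B-scan time series, SHG fields.
#' Frames are stored as a 3-D array indexed `[time, row, column]` with a
#' top-left origin; for B-scans, depth increases with the row index.
#'
#' @param frames 3-D numeric array `(time, row, column)`, finite, non-negative
#' @param pixel_size physical pixel size, micrometres per pixel
#' @param frame_rate acquisition rate, frames per second
#' @param metadata free-form provenance list; generators store `seed` and a
#'   `ground_truth` reference here
#' @return an object of class `image_stack`
#' @export
image_stack <- function(frames, pixel_size, frame_rate, metadata = list()) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop_invalid("`frames` must be a 3-D array (time, row, column)")
  if (any(!is.finite(frames)) || any(frames < 0))
    stop_invalid("frame intensities must be finite and non-negative")
  assert_positive(pixel_size, "pixel_size")
  assert_positive(frame_rate, "frame_rate")
  structure(
    list(frames = frames, pixel_size = pixel_size, frame_rate = frame_rate,
         metadata = metadata),
    class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frames of %d x %d px (%.3g um/px, %g fps)\n",
              d[1], d[2], d[3], x$pixel_size, x$frame_rate))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$frames)

#' Write an image stack as plain-text frames with a JSON sidecar
#'
#' One whitespace-delimited matrix file per frame (`frame_0001.txt`, ...) plus
#' `stack.json` holding pixel size, frame rate and metadata (including any
#' ground truth). A text-based stand-in for multi-page TIFF.
#'
#' @param stack an [image_stack()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_image_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "image_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(stack$frames)
  for (t in seq_len(d[1])) {
    utils::write.table(
      stack$frames[t, , , drop = TRUE],
      file.path(dir, sprintf("frame_%04d.txt", t)),
      row.names = FALSE, col.names = FALSE)
  }
  side <- list(pixel_size = stack$pixel_size, frame_rate = stack$frame_rate,
               n_frames = d[1], n_rows = d[2], n_cols = d[3],
               metadata = stack$metadata)
  jsonlite::write_json(side, file.path(dir, "stack.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param dir directory containing `frame_*.txt` and `stack.json`
#' @return an [image_stack()]
#' @export
read_image_stack <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "stack.json"), simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.txt$", full.names = TRUE))
  if (length(files) != side$n_frames)
    stop_invalid("stack directory lists %d frames but sidecar says %d",
                 length(files), side$n_frames)
  frames <- array(0, dim = c(side$n_frames, side$n_rows, side$n_cols))
  for (t in seq_along(files)) {
    frames[t, , ] <- as.matrix(utils::read.table(files[t]))
  }
  image_stack(frames, side$pixel_size, side$frame_rate,
              metadata = if (is.null(side$metadata)) list() else side$metadata)
}
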