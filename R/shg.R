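# Fibrillar-collagen quantification and stereology: threshold area
# fractions, lung-volume normalization, Cavalieri volumes, point counting.

#' Otsu's threshold
#'
#' Maximizes between-class variance on a 256-bin histogram of the image.
#'
#' @param img numeric matrix
#' @return threshold value, or NA for a constant image
#' @export
otsu_threshold <- function(img) {
  rng <- range(img)
  if (diff(rng) <= 0) return(NA_real_)
  h <- graphics::hist(img, breaks = seq(rng[1], rng[2], length.out = 257),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sb <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- 0
  mids[which.max(sb)]
}

#' Percent area covered by fibrillar collagen in one field
#'
#' `100 * (pixels above threshold) / (total pixels)`.
#'
#' @param field single-channel image matrix (or logical mask)
#' @param threshold_method "otsu" (default) or "fixed"
#' @param threshold threshold value for `"fixed"`, and the fallback used
#'   (with a warning) when Otsu is undefined on a constant image (default 0)
#' @return percent area in \[0, 100\]
#' @export
collagen_area_fraction <- function(field, threshold_method = c("otsu", "fixed"),
                                   threshold = 0) {
  threshold_method <- match.arg(threshold_method)
  if (is.logical(field)) return(100 * mean(field))
  thr <- if (threshold_method == "fixed") threshold else otsu_threshold(field)
  if (is.na(thr)) {
    warning("constant image: Otsu undefined, falling back to fixed threshold")
    thr <- threshold
  }
  100 * mean(field > thr)
}

#' Normalize area fractions to lung volumes
#'
#' Default rule is multiplicative against a cohort reference:
#' `normalized = percent_area * lung_volume / reference_volume`, with the
#' reference defaulting to the cohort mean volume. `rule = "divide"` gives
#' the reciprocal convention.
#'
#' @param percent_area numeric vector of per-record percent areas
#' @param lung_volume per-record lung volumes, mm^3 (> 0)
#' @param reference_volume scalar reference, mm^3; default `mean(lung_volume)`
#' @param rule "multiply" (default) or "divide"
#' @return numeric vector of normalized fractions
#' @export
normalize_to_volume <- function(percent_area, lung_volume,
                                reference_volume = NULL,
                                rule = c("multiply", "divide")) {
  rule <- match.arg(rule)
  if (any(!is.finite(lung_volume)) || any(lung_volume <= 0))
    stop_invalid("lung volumes must be positive")
  if (is.null(reference_volume)) reference_volume <- mean(lung_volume)
  assert_positive(reference_volume, "reference_volume")
  if (rule == "multiply") percent_area * lung_volume / reference_volume
  else percent_area * reference_volume / lung_volume
}

#' Cavalieri volume estimate
#'
#' `volume = slice_thickness * sum(slice_areas)` — the unbiased stereological
#' estimator from uniformly spaced sections.
#'
#' @param slice_areas section areas, mm^2 (non-negative)
#' @param slice_thickness section spacing, mm (> 0)
#' @return volume, mm^3
#' @export
cavalieri_volume <- function(slice_areas, slice_thickness) {
  if (length(slice_areas) < 1L) stop_invalid("need >= 1 slice")
  if (any(!is.finite(slice_areas)) || any(slice_areas < 0))
    stop_invalid("slice areas must be non-negative")
  assert_positive(slice_thickness, "slice_thickness")
  slice_thickness * sum(slice_areas)
}

#' Area fraction by point counting
#'
#' Fraction of regular grid points hitting foreground; the grid offset is
#' randomized by seed, which is what makes the estimator unbiased.
#'
#' @param field image matrix or logical mask
#' @param grid_spacing grid spacing in pixels (>= 1)
#' @param seed RNG seed for the grid offset
#' @param threshold_method,threshold as in [collagen_area_fraction()]
#'   (ignored for logical masks)
#' @return fraction in \[0, 1\]
#' @export
point_count_fraction <- function(field, grid_spacing, seed,
                                 threshold_method = "otsu", threshold = 0) {
  grid_spacing <- assert_count(grid_spacing, "grid_spacing")
  seed <- assert_seed(seed)
  if (grid_spacing > min(dim(field)))
    stop_invalid("grid_spacing (%d) exceeds image size (%d x %d)",
                 grid_spacing, nrow(field), ncol(field))
  mask <- if (is.logical(field)) field else {
    thr <- if (threshold_method == "fixed") threshold else otsu_threshold(field)
    if (is.na(thr)) thr <- threshold
    field > thr
  }
  off <- with_seed(seed, sample.int(grid_spacing, 2L, replace = TRUE))
  rows <- seq(off[1], nrow(mask), by = grid_spacing)
  cols <- seq(off[2], ncol(mask), by = grid_spacing)
  mean(mask[rows, cols])
}

#' Area-fraction records for a cohort of SHG field sets
#'
#' @param field_sets named list (by animal) of [simulate_shg_field_set()]
#'   outputs or lists of image matrices
#' @param group_id group label recycled across animals
#' @param threshold_method,threshold as in [collagen_area_fraction()]
#' @return data.frame: `animal_id`, `group_id`, `field_id`, `percent_area`
#' @export
area_fraction_records <- function(field_sets, group_id = "group",
                                  threshold_method = "otsu", threshold = 0) {
  rows <- lapply(names(field_sets), function(an) {
    fs <- field_sets[[an]]
    fields <- if (inherits(fs, "shg_field_set")) fs$fields else fs
    data.frame(animal_id = an, group_id = group_id,
               field_id = seq_along(fields),
               percent_area = vapply(fields, collagen_area_fraction,
                                     numeric(1),
                                     threshold_method = threshold_method,
                                     threshold = threshold))
  })
  do.call(rbind, rows)
}
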